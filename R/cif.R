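# Monomer-library style restraint CIF: chem_comp_bond / chem_comp_angle /
# chem_comp_chir loops for the component, chem_link_bond / chem_link_angle
# for the SF4-CYS link. One data block per component or link. Values are
# printed at 3 decimals (Angstrom) and 2 decimals (degrees); reading
# returns exactly the printed values, so write -> read round-trips at
# printed precision.

.fmt_a <- function(x) sprintf("%.3f", x)
.fmt_deg <- function(x) sprintf("%.2f", x)

#' Write a restraint dictionary CIF
#'
#' Serializes an [restraint_set()] (component block `data_comp_SF4` with
#' bond, angle and chirality loops) or a [link_definition()] (block
#' `data_link_SF4-CYS` with link bond and angle loops). Output is
#' deterministic: identical input yields byte-identical files.
#'
#' @param x An `sf4_restraints` or `sf4_link` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints_cif <- function(x, path) {
  lines <- if (inherits(x, "sf4_restraints")) {
    .comp_cif_lines(x)
  } else if (inherits(x, "sf4_link")) {
    .link_cif_lines(x)
  } else {
    stop("write_restraints_cif needs an sf4_restraints or sf4_link object",
         call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

.comp_cif_lines <- function(x) {
  c(
    "data_comp_list",
    "loop_",
    "_chem_comp.id",
    "_chem_comp.name",
    "_chem_comp.group",
    "_chem_comp.number_atoms_all",
    sprintf("%s 'IRON/SULFUR CLUSTER' non-polymer 8", x$comp_id),
    "#",
    paste0("data_comp_", x$comp_id),
    "loop_",
    "_chem_comp_bond.comp_id",
    "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    "_chem_comp_bond.type",
    "_chem_comp_bond.value_dist",
    "_chem_comp_bond.value_dist_esd",
    sprintf("%s %-4s %-4s single %s %s", x$comp_id,
            x$bonds$atom_1, x$bonds$atom_2,
            .fmt_a(x$bonds$value), .fmt_a(x$bonds$sigma)),
    "#",
    "loop_",
    "_chem_comp_angle.comp_id",
    "_chem_comp_angle.atom_id_1",
    "_chem_comp_angle.atom_id_2",
    "_chem_comp_angle.atom_id_3",
    "_chem_comp_angle.value_angle",
    "_chem_comp_angle.value_angle_esd",
    sprintf("%s %-4s %-4s %-4s %s %s", x$comp_id,
            x$angles$atom_1, x$angles$atom_2, x$angles$atom_3,
            .fmt_deg(x$angles$value), .fmt_deg(x$angles$sigma)),
    "#",
    if (nrow(x$chirals) > 0) c(
      "loop_",
      "_chem_comp_chir.comp_id",
      "_chem_comp_chir.id",
      "_chem_comp_chir.atom_id_centre",
      "_chem_comp_chir.atom_id_1",
      "_chem_comp_chir.atom_id_2",
      "_chem_comp_chir.atom_id_3",
      "_chem_comp_chir.volume_sign",
      sprintf("%s %s %-4s %-4s %-4s %-4s %s", x$comp_id,
              x$chirals$id, x$chirals$center, x$chirals$atom_1,
              x$chirals$atom_2, x$chirals$atom_3, x$chirals$sign),
      "#"))
}

.link_cif_lines <- function(x) {
  c(
    paste0("data_link_", x$link_id),
    "loop_",
    "_chem_link_bond.link_id",
    "_chem_link_bond.atom_1_comp_id",
    "_chem_link_bond.atom_id_1",
    "_chem_link_bond.atom_2_comp_id",
    "_chem_link_bond.atom_id_2",
    "_chem_link_bond.value_dist",
    "_chem_link_bond.value_dist_esd",
    sprintf("%s %s %s %s %s %s %s", x$link_id,
            x$bond$comp_1, x$bond$atom_1, x$bond$comp_2, x$bond$atom_2,
            .fmt_a(x$bond$value), .fmt_a(x$bond$sigma)),
    "#",
    "loop_",
    "_chem_link_angle.link_id",
    "_chem_link_angle.atom_1_comp_id",
    "_chem_link_angle.atom_id_1",
    "_chem_link_angle.atom_2_comp_id",
    "_chem_link_angle.atom_id_2",
    "_chem_link_angle.atom_3_comp_id",
    "_chem_link_angle.atom_id_3",
    "_chem_link_angle.value_angle",
    "_chem_link_angle.value_angle_esd",
    sprintf("%s %s %s %s %s %s %s %s %s", x$link_id,
            x$angle$comp_1, x$angle$atom_1, x$angle$comp_2, x$angle$atom_2,
            x$angle$comp_3, x$angle$atom_3,
            .fmt_deg(x$angle$value), .fmt_deg(x$angle$sigma)),
    "#")
}

# ---- reading ---------------------------------------------------------------

# Tokenize one CIF line, honouring single/double quotes.
.cif_tokens <- function(line) {
  out <- character()
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (substr(rest, 1, 1) %in% c("'", '"')) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) return(NULL)
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substr(rest, end + 2, nchar(rest)))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) {
        out <- c(out, rest)
        rest <- ""
      } else {
        out <- c(out, substr(rest, 1, sp - 1))
        rest <- trimws(substr(rest, sp, nchar(rest)))
      }
    }
  }
  out
}

# Parse all loops in a CIF file: returns list of data.frames keyed by the
# loop's tag category (e.g. "_chem_comp_bond"), plus the data block names.
.parse_cif_loops <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loops <- list()
  blocks <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^data_", line)) {
      blocks <- c(blocks, sub("^data_", "", line))
      i <- i + 1L
    } else if (line == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i]))
        i <- i + 1L
      }
      if (!length(tags)) {
        stop("malformed CIF at line ", i, ": loop_ without tags",
             call. = FALSE)
      }
      rows <- list()
      while (i <= n) {
        l <- trimws(lines[i])
        if (l == "" || grepl("^#", l)) { i <- i + 1L; next }
        if (grepl("^(data_|loop_|_)", l)) break
        tok <- .cif_tokens(l)
        if (is.null(tok)) {
          stop("malformed CIF at line ", i, ": unterminated quote",
               call. = FALSE)
        }
        if (length(tok) != length(tags)) {
          stop("malformed CIF at line ", i, ": expected ", length(tags),
               " values, found ", length(tok), call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- tok
        i <- i + 1L
      }
      cat_name <- sub("\\..*$", "", tags[1])
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(df) <- sub("^[^.]*\\.", "", tags)
      loops[[cat_name]] <- df
    } else {
      i <- i + 1L
    }
  }
  list(loops = loops, blocks = blocks)
}

#' Read a restraint dictionary CIF
#'
#' Reads a file in the dialect emitted by [write_restraints_cif()]:
#' returns an `sf4_restraints` object when the file holds a component
#' block, or an `sf4_link` when it holds a link block. A component file
#' without a chirality loop is accepted with a warning (zero chiral
#' restraints). The geometry label is inferred from the angle targets
#' (both classes at 90 degrees reads as cubic).
#'
#' @param path Path to the CIF file.
#' @return An `sf4_restraints` or `sf4_link` object.
#' @export
read_restraints_cif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- .parse_cif_loops(path)
  loops <- parsed$loops
  if (!is.null(loops$`_chem_comp_bond`)) {
    return(.restraints_from_loops(loops))
  }
  if (!is.null(loops$`_chem_link_bond`)) {
    return(.link_from_loops(loops))
  }
  stop("no chem_comp_bond or chem_link_bond loop found in ", path,
       call. = FALSE)
}

.restraints_from_loops <- function(loops) {
  b <- loops$`_chem_comp_bond`
  comp <- unique(b$comp_id)
  if (length(comp) != 1L || comp != "SF4") {
    stop("unsupported component: expected comp_id SF4, found ",
         paste(comp, collapse = ", "), call. = FALSE)
  }
  a <- loops$`_chem_comp_angle`
  if (is.null(a)) {
    stop("component block is missing the chem_comp_angle loop",
         call. = FALSE)
  }
  bonds <- tibble::tibble(atom_1 = b$atom_id_1, atom_2 = b$atom_id_2,
                          value = as.numeric(b$value_dist),
                          sigma = as.numeric(b$value_dist_esd))
  is_fesfe <- grepl("^FE", a$atom_id_1) & grepl("^S", a$atom_id_2)
  angles <- tibble::tibble(
    class = ifelse(is_fesfe, "Fe-S-Fe", "S-Fe-S"),
    atom_1 = a$atom_id_1, atom_2 = a$atom_id_2, atom_3 = a$atom_id_3,
    value = as.numeric(a$value_angle),
    sigma = as.numeric(a$value_angle_esd))
  ch <- loops$`_chem_comp_chir`
  if (is.null(ch)) {
    warning("no chirality loop found; restraint set has 0 chiral restraints",
            call. = FALSE)
    chirals <- .chiral_rows()[0, ]
  } else {
    chirals <- tibble::tibble(id = ch$id, center = ch$atom_id_centre,
                              atom_1 = ch$atom_id_1, atom_2 = ch$atom_id_2,
                              atom_3 = ch$atom_id_3, sign = ch$volume_sign)
  }
  mean_fesfe <- mean(angles$value[angles$class == "Fe-S-Fe"])
  mean_sfes <- mean(angles$value[angles$class == "S-Fe-S"])
  label <- if (abs(mean_fesfe - 90) < 1e-9 && abs(mean_sfes - 90) < 1e-9)
    "cubic" else "rhomboid"
  structure(list(comp_id = comp, label = label, bonds = bonds,
                 angles = angles, chirals = chirals),
            class = "sf4_restraints")
}

.link_from_loops <- function(loops) {
  b <- loops$`_chem_link_bond`
  a <- loops$`_chem_link_angle`
  if (is.null(a)) {
    stop("link block is missing the chem_link_angle loop", call. = FALSE)
  }
  structure(list(
    link_id = b$link_id[1],
    bond = tibble::tibble(atom_1 = b$atom_id_1, comp_1 = b$atom_1_comp_id,
                          atom_2 = b$atom_id_2, comp_2 = b$atom_2_comp_id,
                          value = as.numeric(b$value_dist),
                          sigma = as.numeric(b$value_dist_esd)),
    angle = tibble::tibble(atom_1 = a$atom_id_1, comp_1 = a$atom_1_comp_id,
                           atom_2 = a$atom_id_2, comp_2 = a$atom_2_comp_id,
                           atom_3 = a$atom_id_3, comp_3 = a$atom_3_comp_id,
                           value = as.numeric(a$value_angle),
                           sigma = as.numeric(a$value_angle_esd))),
    class = "sf4_link")
}
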