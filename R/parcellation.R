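# Parcellation: combined cortical/subcortical region table, homologue
# pairing, and the two coordinate systems (anatomical mm, unit sphere)
# consumed by the spatial null models.

dk_cortical_names <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

subcortical_names <- c(
  "thalamus", "caudate", "putamen", "pallidum", "amygdala", "accumbens",
  "hippocampus")

# Quasi-uniform points on a spherical cap around the pole (0, 0, 1),
# golden-angle azimuths; cap_depth in (0, 2] controls cap extent.
.cap_points <- function(n, cap_depth = 1.6) {
  i <- seq_len(n) - 1
  t <- (i + 0.5) / n
  cz <- 1 - cap_depth * t
  r <- sqrt(pmax(0, 1 - cz^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), cz)
}

# Synthetic-but-plausible coordinates for the default 82-region table:
# cortical regions on two hemispheric caps, subcortical structures near the
# inter-hemispheric axis, below the cortical sheet.
.synthetic_coords <- function() {
  nc <- length(dk_cortical_names)
  cap <- .cap_points(nc)
  # proper rotation taking the cap pole e_z to -e_x (left hemisphere)
  rot <- rbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
  left_ctx <- cap %*% t(rot)
  right_ctx <- left_ctx
  right_ctx[, 1] <- -right_ctx[, 1]

  ns <- length(subcortical_names)
  j <- seq_len(ns) - 1
  ang <- pi * (j + 0.5) / ns
  left_sub <- cbind(-0.22, 0.9 * cos(ang), -0.35 - 0.4 * sin(ang))
  left_sub <- left_sub / sqrt(rowSums(left_sub^2))
  right_sub <- left_sub
  right_sub[, 1] <- -right_sub[, 1]

  list(left_ctx = left_ctx, right_ctx = right_ctx,
       left_sub = left_sub, right_sub = right_sub)
}

#' Default 82-region combined cortical/subcortical parcellation
#'
#' Builds the packaged region table: 68 Desikan-Killiany cortical regions
#' (34 per hemisphere) and 14 subcortical structures (bilateral thalamus,
#' caudate, putamen, pallidum, amygdala, accumbens, and hippocampus).
#' Region order is fixed: cortical homologue pairs first (left before right
#' within each pair), then subcortical pairs. Coordinates are synthetic but
#' spatially plausible -- cortical regions lie on two hemispheric caps of
#' the unit sphere and subcortical regions sit near the inter-hemispheric
#' axis -- and users with real surface models may supply their own table
#' through [load_region_table()].
#'
#' @return A validated region table (`data.frame`) with columns `region_id`
#'   (0-based), `name`, `hemisphere`, `class`, `homologue`, `homologue_id`,
#'   anatomical coordinates `x`, `y`, `z` (mm) and unit-sphere coordinates
#'   `sx`, `sy`, `sz`.
#' @export
default_region_table <- function() {
  co <- .synthetic_coords()
  rows <- list()
  add <- function(name, hemi, cls, hom, sphere, radius) {
    data.frame(name = name, hemisphere = hemi, class = cls, homologue = hom,
               x = sphere[1] * radius, y = sphere[2] * radius,
               z = sphere[3] * radius,
               sx = sphere[1], sy = sphere[2], sz = sphere[3],
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(dk_cortical_names)) {
    nm <- dk_cortical_names[i]
    rows[[length(rows) + 1L]] <- add(paste0("L_", nm), "left", "cortical",
                                     paste0("R_", nm), co$left_ctx[i, ], 70)
    rows[[length(rows) + 1L]] <- add(paste0("R_", nm), "right", "cortical",
                                     paste0("L_", nm), co$right_ctx[i, ], 70)
  }
  for (i in seq_along(subcortical_names)) {
    nm <- subcortical_names[i]
    rows[[length(rows) + 1L]] <- add(paste0("L_", nm), "left", "subcortical",
                                     paste0("R_", nm), co$left_sub[i, ], 25)
    rows[[length(rows) + 1L]] <- add(paste0("R_", nm), "right", "subcortical",
                                     paste0("L_", nm), co$right_sub[i, ], 25)
  }
  tbl <- do.call(rbind, rows)
  validate_region_table(tbl)
}

#' Validate a region table
#'
#' Checks required columns, unique names, a symmetric fixed-point-free
#' homologue pairing, and unit-norm sphere coordinates, then attaches
#' 0-based `region_id` and `homologue_id` columns. All matrices produced by
#' the pipeline are indexed identically to the rows of this table.
#'
#' @param tbl data.frame with columns `name`, `hemisphere`, `class`,
#'   `homologue`, `x`, `y`, `z`, `sx`, `sy`, `sz`.
#' @return The validated table with `region_id` and `homologue_id` added.
#' @export
validate_region_table <- function(tbl) {
  req <- c("name", "hemisphere", "class", "homologue",
           "x", "y", "z", "sx", "sy", "sz")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0)
    stop("region table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tbl$name))
    stop("region table has duplicate region name(s): ",
         paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", "))
  if (!all(tbl$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (!all(tbl$class %in% c("cortical", "subcortical")))
    stop("class must be 'cortical' or 'subcortical'")
  hom_idx <- match(tbl$homologue, tbl$name)
  if (anyNA(hom_idx))
    stop("homologue name(s) not found in table: ",
         paste(tbl$homologue[is.na(hom_idx)], collapse = ", "))
  if (any(hom_idx == seq_len(nrow(tbl))))
    stop("homologue pairing maps region(s) to themselves: ",
         paste(tbl$name[hom_idx == seq_len(nrow(tbl))], collapse = ", "))
  if (!all(hom_idx[hom_idx] == seq_len(nrow(tbl))))
    stop("homologue pairing is not symmetric")
  norms <- sqrt(tbl$sx^2 + tbl$sy^2 + tbl$sz^2)
  if (any(abs(norms - 1) > 1e-9))
    stop("sphere coordinates are not unit-norm (max deviation ",
         format(max(abs(norms - 1))), ")")
  tbl$region_id <- seq_len(nrow(tbl)) - 1L
  tbl$homologue_id <- hom_idx - 1L
  rownames(tbl) <- NULL
  tbl
}

#' Load a region table from CSV
#'
#' Reads a region annotation table (columns `name`, `hemisphere`, `class`,
#' `homologue`, `x`, `y`, `z`, `sx`, `sy`, `sz`) and validates it. The row
#' order of the file is preserved and defines region indices, so repeated
#' loads of the same file give identical orderings.
#'
#' @param path path to a CSV file.
#' @return validated region table, see [validate_region_table()].
#' @export
load_region_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(tbl)
}

#' Homologue swap permutation
#'
#' Permutation of region indices exchanging every region with its
#' contralateral homologue; applying it twice is the identity. Used to
#' reorder right-focus subjects so that indices mean ipsilateral /
#' contralateral rather than left / right.
#'
#' @param tbl validated region table.
#' @return integer vector `p` (1-based) such that region `i` maps to
#'   `p[i]`, its homologue.
#' @export
hemisphere_swap_order <- function(tbl) {
  if (is.null(tbl$homologue_id)) tbl <- validate_region_table(tbl)
  tbl$homologue_id + 1L
}

#' Path to the packaged synthetic 82-region table
#'
#' @return file path of the CSV shipped with the package.
#' @export
default_region_table_path <- function() {
  system.file("extdata", "regions_dk82_synthetic.csv", package = "covnet",
              mustWork = TRUE)
}
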