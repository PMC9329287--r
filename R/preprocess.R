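# Preprocessing: imputation/exclusion, age+sex residualization,
# z-scoring against site-matched controls, ipsi/contra sorting.

meta_columns <- c("subject_id", "site", "group", "age", "sex", "focus_side")

.check_subject_table <- function(subjects, region_table) {
  missing_cols <- setdiff(meta_columns, names(subjects))
  if (length(missing_cols) > 0)
    stop("subject table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  missing_reg <- setdiff(region_table$name, names(subjects))
  if (length(missing_reg) > 0)
    stop("subject table is missing region column(s): ",
         paste(utils::head(missing_reg, 5), collapse = ", "),
         if (length(missing_reg) > 5) " ..." else "")
  bad <- subjects$group == "TLE" & !(subjects$focus_side %in% c("left", "right"))
  if (any(bad))
    stop("TLE subject(s) without a seizure-focus side: ",
         paste(subjects$subject_id[bad], collapse = ", "))
  invisible(subjects)
}

#' Exclude incomplete subjects and impute remaining missing values
#'
#' Subjects missing at least half of the cortical measures or at least half
#' of the subcortical measures are removed. Each remaining missing value is
#' replaced by the mean of that region over the non-missing subjects of the
#' same site and diagnostic group.
#'
#' @param subjects data.frame with columns `subject_id`, `site`, `group`
#'   (`"TLE"`, `"IGE"` or `"HC"`), `age`, `sex`, `focus_side`, followed by
#'   one column per region named as in the region table. `NA` marks a
#'   missing measurement.
#' @param region_table validated region table, see [load_region_table()].
#' @return the subject table with excluded rows dropped and `NA`s imputed;
#'   attribute `n_excluded` records the number of removed subjects.
#' @export
impute_and_filter <- function(subjects, region_table) {
  .check_subject_table(subjects, region_table)
  if (nrow(subjects) == 0) stop("empty cohort")
  ctx <- region_table$name[region_table$class == "cortical"]
  sub <- region_table$name[region_table$class == "subcortical"]
  miss_ctx <- rowSums(is.na(subjects[, ctx, drop = FALSE]))
  miss_sub <- rowSums(is.na(subjects[, sub, drop = FALSE]))
  drop <- miss_ctx >= length(ctx) / 2 | miss_sub >= length(sub) / 2
  kept <- subjects[!drop, , drop = FALSE]
  if (nrow(kept) == 0) stop("all subjects excluded by the missingness rule")
  key <- interaction(kept$site, kept$group, drop = TRUE)
  for (rg in region_table$name) {
    v <- kept[[rg]]
    if (!anyNA(v)) next
    mu <- tapply(v, key, function(x) mean(x, na.rm = TRUE))
    if (anyNA(mu) || any(!is.finite(mu))) {
      bad <- names(mu)[!is.finite(mu)]
      stop("region '", rg, "' is missing in every subject of site-group(s): ",
           paste(bad, collapse = ", "))
    }
    v[is.na(v)] <- mu[as.character(key)][is.na(v)]
    kept[[rg]] <- v
  }
  attr(kept, "n_excluded") <- sum(drop)
  kept
}

#' Residualize for age and sex, then z-score against site-matched controls
#'
#' Per site and region, values are regressed on an intercept, age, and sex
#' (ordinary least squares over the site's pooled patients and controls);
#' residuals are then standardized with the mean and standard deviation of
#' that site's control residuals, so control columns have mean 0 and SD 1
#' within every site. Residuals are invariant to the (0/1) sex coding.
#'
#' @param subjects imputed subject table, see [impute_and_filter()].
#' @param region_table validated region table.
#' @return an object of class `covnet_cohort`: list with `values`
#'   (subjects x regions z-score matrix), `meta` (demographics), `regions`
#'   (region names) and `coefficients` (per-site regression coefficients).
#' @export
residualize_and_zscore <- function(subjects, region_table) {
  .check_subject_table(subjects, region_table)
  regions <- region_table$name
  vals <- as.matrix(subjects[, regions, drop = FALSE])
  if (anyNA(vals)) stop("missing values remain; run impute_and_filter() first")
  sexnum <- as.numeric(factor(subjects$sex)) - 1
  z <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(subjects$subject_id, regions))
  coefs <- list()
  for (s in unique(subjects$site)) {
    idx <- subjects$site == s
    is_hc <- subjects$group[idx] == "HC"
    if (sum(is_hc) < 2)
      stop("site '", s, "' has fewer than 2 controls")
    X <- cbind(1, subjects$age[idx], sexnum[idx])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X))
      stop("singular age/sex design at site '", s,
           "' (constant covariate?)")
    beta <- qr.coef(qr_x, vals[idx, , drop = FALSE])
    resid <- vals[idx, , drop = FALSE] - X %*% beta
    mu <- colMeans(resid[is_hc, , drop = FALSE])
    sd0 <- apply(resid[is_hc, , drop = FALSE], 2, stats::sd)
    if (any(sd0 == 0))
      stop("control residual SD is zero at site '", s, "' for region(s): ",
           paste(regions[sd0 == 0], collapse = ", "))
    z[idx, ] <- sweep(sweep(resid, 2, mu), 2, sd0, "/")
    coefs[[s]] <- beta
  }
  structure(list(values = z,
                 meta = subjects[, meta_columns, drop = FALSE],
                 regions = regions,
                 coefficients = coefs,
                 sorted_ipsi_contra = FALSE),
            class = "covnet_cohort")
}

#' Reorder regions of right-focus patients into ipsi/contra convention
#'
#' Right-focus TLE subjects have their region values permuted by the
#' homologue swap so that, after sorting, a given column means
#' "ipsilateral to the focus" (respectively contralateral) for every
#' patient. Left-focus patients and controls are left untouched (controls
#' keep the left-hemisphere-as-ipsilateral convention). The operation is an
#' involution on each affected subject.
#'
#' @param cohort `covnet_cohort` from [residualize_and_zscore()].
#' @param region_table validated region table.
#' @return the cohort with right-focus rows permuted and
#'   `sorted_ipsi_contra` toggled.
#' @export
sort_ipsi_contra <- function(cohort, region_table) {
  stopifnot(inherits(cohort, "covnet_cohort"))
  perm <- hemisphere_swap_order(region_table)
  is_tle <- cohort$meta$group == "TLE"
  side <- cohort$meta$focus_side
  if (any(is_tle & !(side %in% c("left", "right"))))
    stop("TLE subject(s) without focus side; cannot sort ipsi/contra")
  flip <- is_tle & side == "right"
  cohort$values[flip, ] <- cohort$values[flip, perm, drop = FALSE]
  cohort$sorted_ipsi_contra <- !isTRUE(cohort$sorted_ipsi_contra)
  cohort
}

#' @export
print.covnet_cohort <- function(x, ...) {
  cat("covnet cohort:", nrow(x$values), "subjects x", ncol(x$values),
      "regions;", length(unique(x$meta$site)), "site(s);",
      "groups:", paste(names(table(x$meta$group)),
                       table(x$meta$group), collapse = ", "), "\n")
  invisible(x)
}
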