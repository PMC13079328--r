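#' Amyloid positivity from PET SUVR
#'
#' Classifies a cortical standardized uptake value ratio against the
#' tracer-specific threshold: 1.11 for florbetapir (FBP) and 1.08 for
#' florbetaben (FBB). The comparison is inclusive: a SUVR exactly at the
#' threshold is positive.
#'
#' @param suvr numeric vector of SUVRs (> 0); `NA` propagates.
#' @param tracer character vector, `"FBP"` or `"FBB"` (recycled).
#' @return Character vector `"positive"` / `"negative"` (`NA` where
#'   `suvr` is `NA`).
#' @export
classify_amyloid <- function(suvr, tracer) {
  thresholds <- c(FBP = 1.11, FBB = 1.08)
  if (any(!tracer[!is.na(tracer)] %in% names(thresholds)))
    stop("unknown tracer; expected FBP or FBB", call. = FALSE)
  if (any(suvr <= 0, na.rm = TRUE)) stop("SUVR must be > 0", call. = FALSE)
  out <- ifelse(suvr >= thresholds[tracer], "positive", "negative")
  out[is.na(suvr)] <- NA_character_
  unname(out)
}

#' APOE-e4 carrier status from a genotype
#'
#' Carrier iff at least one e4 allele (heterozygous or homozygous).
#' Genotypes are slash-separated allele pairs, e.g. `"e3/e4"`; the
#' epsilon may be spelled `e` or the Unicode epsilon.
#'
#' @param genotype character vector of allele pairs; `NA` propagates.
#' @return Character vector `"carrier"` / `"non_carrier"`.
#' @export
classify_apoe <- function(genotype) {
  out <- rep(NA_character_, length(genotype))
  ok <- !is.na(genotype)
  norm <- gsub("ε", "e", genotype[ok])
  parts <- strsplit(norm, "/", fixed = TRUE)
  valid <- vapply(parts, function(p)
    length(p) == 2L && all(p %in% c("e2", "e3", "e4")), logical(1))
  if (any(!valid))
    stop("malformed genotype: ", paste(genotype[ok][!valid],
         collapse = ", "), call. = FALSE)
  out[ok] <- ifelse(vapply(parts, function(p) any(p == "e4"), logical(1)),
                    "carrier", "non_carrier")
  out
}

#' Percentage cell with half-up rounding to two decimals
#'
#' Demographic-table arithmetic: `100 * count / denominator`, rounded
#' half-up (so 0.005 rounds to 0.01, unlike banker's rounding).
#'
#' @param count integer >= 0, `count <= denominator`.
#' @param denominator integer > 0; typically the group n minus the number
#'   missing for the variable.
#' @return Percentage rounded to 2 decimals.
#' @export
cell_percentage <- function(count, denominator) {
  if (any(denominator <= 0)) stop("zero denominator", call. = FALSE)
  if (any(count < 0) || any(count > denominator))
    stop("count must be in [0, denominator]", call. = FALSE)
  floor(100 * count / denominator * 100 + 0.5) / 100
}

#' Demographic comparison table
#'
#' For each categorical variable, a Pearson chi-squared test (no
#' continuity correction) on the group-by-level contingency table; for
#' each continuous variable, two-sided Student's t-tests with pooled
#' variance (all pairwise tests when there are more than two groups;
#' Welch available via `var_equal = FALSE`). Cells with zero expected
#' count flag the test as unreliable rather than failing.
#'
#' @param data data.frame with one row per subject.
#' @param group name of the grouping column (>= 2 levels, each with >= 2
#'   rows).
#' @param categorical,continuous character vectors of column names.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return A list of class `cohort_summary`: `groups` (per-group n),
#'   `categorical` (per-variable cell counts, percentages against the
#'   group n minus missing, chi-squared statistic, df, p, reliability
#'   flag) and `continuous` (per-group mean and SD plus pairwise t, df,
#'   p).
#' @export
demographic_tests <- function(data, group, categorical = character(0),
                              continuous = character(0),
                              var_equal = TRUE) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 rows", call. = FALSE)
  cat_out <- list()
  for (v in categorical) {
    x <- data[[v]]
    keep <- !is.na(x)
    tab <- table(g[keep], x[keep])
    denom <- rowSums(tab)
    pct <- tab
    pct[] <- cell_percentage(as.integer(tab),
                             rep(pmax(denom, 1L), times = ncol(tab)))
    expected_zero <- any(outer(rowSums(tab), colSums(tab)) == 0)
    test <- suppressWarnings(chisq.test(tab, correct = FALSE))
    cat_out[[v]] <- list(counts = tab, percentages = pct,
                         n_missing = sum(!keep),
                         statistic = unname(test$statistic),
                         df = unname(test$parameter),
                         p_value = unname(test$p.value),
                         reliable = !expected_zero)
  }
  cont_out <- list()
  lev <- levels(g)
  for (v in continuous) {
    x <- data[[v]]
    by_group <- data.frame(
      group = lev,
      n = as.integer(tapply(!is.na(x), g, sum)),
      mean = as.numeric(tapply(x, g, mean, na.rm = TRUE)),
      sd = as.numeric(tapply(x, g, sd, na.rm = TRUE)))
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      tt <- t.test(x[g == p[1]], x[g == p[2]], var.equal = var_equal)
      data.frame(group1 = p[1], group2 = p[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    }))
    cont_out[[v]] <- list(by_group = by_group, tests = tests)
  }
  structure(list(groups = table(g), categorical = cat_out,
                 continuous = cont_out), class = "cohort_summary")
}
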