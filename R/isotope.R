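# Preprocessing and univariate niche metrics for trivariate isotope tables:
# arithmetic lipid correction of delta-13C from the tissue C:N ratio, Layman
# range metrics (CR/NR/SR), and Mardia's multivariate normality test with the
# small-sample skewness correction.

ISOTOPE_COLS <- c("species", "area", "total_length_mm",
                  "d13C", "d15N", "d34S", "CN_ratio")

#' Arithmetic lipid correction of delta-13C
#'
#' Lipids are depleted in 13C relative to protein, so bulk delta-13C of
#' high-lipid muscle tissue is corrected by mass balance when the sample C:N
#' ratio exceeds the protein value of 3.7:
#' \deqn{\delta^{13}C_{protein} =
#'   \frac{(\delta^{13}C_{sample} \times C\!:\!N_{sample}) +
#'         7 (C\!:\!N_{sample} - C\!:\!N_{protein})}{C\!:\!N_{sample}}}
#' Samples at or below the threshold are returned unchanged.
#'
#' @param d13c_sample Measured delta-13C values (per mil), vectorized.
#' @param c_to_n Sample C:N ratios (> 0), recycled against `d13c_sample`.
#' @param threshold C:N above which the correction is applied (default 3.7).
#' @param c_to_n_protein Protein C:N ratio (default 3.7, crustacean muscle).
#' @return `data.frame` with columns `d13C` (corrected) and `applied`
#'   (logical flag per value).
#' @examples
#' lipid_correct(-16.0, 4.0)   # (-64 + 2.1)/4 = -15.475, applied
#' lipid_correct(-16.0, 3.7)   # unchanged, rule is strictly "> 3.7"
#' @export
lipid_correct <- function(d13c_sample, c_to_n, threshold = 3.7,
                          c_to_n_protein = 3.7) {
  if (any(!is.finite(c_to_n)) || any(c_to_n <= 0))
    stop("C:N ratios must be positive")
  n <- max(length(d13c_sample), length(c_to_n))
  d13c_sample <- rep_len(as.numeric(d13c_sample), n)
  c_to_n <- rep_len(as.numeric(c_to_n), n)
  applied <- c_to_n > threshold
  corrected <- ifelse(
    applied,
    (d13c_sample * c_to_n + 7 * (c_to_n - c_to_n_protein)) / c_to_n,
    d13c_sample
  )
  data.frame(d13C = corrected, applied = applied)
}

#' Read and validate an isotope table from CSV
#'
#' Expected columns (exact names): `species`, `area`, `total_length_mm`,
#' `d13C`, `d15N`, `d34S`, `CN_ratio`. Rows failing validation (missing
#' isotope values, non-positive C:N, unknown area) are excluded and reported,
#' never silently dropped; delta-34S outside 0-40 per mil draws a warning
#' only. A `lipid_corrected` flag column is added (FALSE) if absent.
#'
#' @param path Path to a CSV file.
#' @return List with `table` (validated `data.frame`) and `excluded`
#'   (`data.frame` of dropped rows with a `reason` column).
#' @export
read_isotope_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_isotope_table(df)
}

#' Validate an in-memory isotope table
#'
#' @param df `data.frame` with the columns described in
#'   [read_isotope_table()].
#' @return List with `table` and `excluded` as in [read_isotope_table()].
#' @export
validate_isotope_table <- function(df) {
  missing_cols <- setdiff(ISOTOPE_COLS, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"lipid_corrected" %in% names(df)) df$lipid_corrected <- FALSE

  reason <- rep(NA_character_, nrow(df))
  iso_na <- !stats::complete.cases(df[, c("d13C", "d15N", "d34S")])
  reason[iso_na] <- "missing isotope value"
  bad_cn <- is.na(reason) & (!is.finite(df$CN_ratio) | df$CN_ratio <= 0)
  reason[bad_cn] <- "non-positive or missing C:N ratio"
  bad_area <- is.na(reason) & !(df$area %in% c("inner", "outer"))
  reason[bad_area] <- "area not in {inner, outer}"

  odd_s <- is.na(reason) & (df$d34S < 0 | df$d34S > 40)
  if (any(odd_s))
    warning(sum(odd_s), " row(s) with delta-34S outside the plausible 0-40 ",
            "per mil range (kept)")

  keep <- is.na(reason)
  excluded <- df[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  list(table = df[keep, , drop = FALSE], excluded = excluded)
}

#' Apply lipid correction to an isotope table
#'
#' Corrects `d13C` in place for rows whose `lipid_corrected` flag is FALSE and
#' whose C:N exceeds the threshold, then sets the flag so that a second call
#' cannot apply the (non-idempotent) correction twice.
#'
#' @param tab Validated isotope table (see [validate_isotope_table()]).
#' @inheritParams lipid_correct
#' @return The table with corrected `d13C` and updated `lipid_corrected`.
#' @export
prepare_isotopes <- function(tab, threshold = 3.7, c_to_n_protein = 3.7) {
  if (!"lipid_corrected" %in% names(tab)) tab$lipid_corrected <- FALSE
  todo <- !tab$lipid_corrected
  if (any(todo)) {
    res <- lipid_correct(tab$d13C[todo], tab$CN_ratio[todo],
                         threshold = threshold,
                         c_to_n_protein = c_to_n_protein)
    tab$d13C[todo] <- res$d13C
    tab$lipid_corrected[todo] <- res$applied
  }
  tab
}

#' Layman range metrics (CR, NR, SR)
#'
#' Max-minus-min of delta-13C, delta-15N and delta-34S over the rows of a
#' group -- the trivariate subset of the community-wide Layman metrics.
#'
#' @param x Isotope table rows for one group (columns `d13C`, `d15N`,
#'   `d34S`), or an n x 3 matrix in that column order.
#' @return Named numeric vector `c(cr = , nr = , sr = )` in per mil.
#' @export
layman_ranges <- function(x) {
  m <- if (is.matrix(x)) x else as.matrix(x[, c("d13C", "d15N", "d34S")])
  if (nrow(m) < 2L)
    stop("range undefined: a group needs at least 2 rows")
  r <- apply(m, 2L, function(v) max(v) - min(v))
  names(r) <- c("cr", "nr", "sr")
  r
}

#' Mardia's multivariate normality test
#'
#' Multivariate skewness and kurtosis statistics from the doubly-centered
#' Mahalanobis inner products \eqn{g_{ij}} (MLE covariance, n denominator):
#' \eqn{b_{1,3} = n^{-2} \sum_{ij} g_{ij}^3} and
#' \eqn{b_{2,3} = n^{-1} \sum_i g_{ii}^2}. The skewness statistic
#' \eqn{n b_{1,3} / 6} is referred to chi-square with 10 df, multiplied by
#' the small-sample correction factor
#' \eqn{(p+1)(n+1)(n+3) / [n((n+1)(p+1) - 6)]} when requested (by default,
#' automatically for n < 20); the kurtosis z-score
#' \eqn{(b_{2,3} - 15)/\sqrt{120/n}} is referred to the standard normal.
#' The verdict is "normal" when both p-values exceed `alpha`. The statistics
#' are invariant under invertible affine transformations of the data.
#'
#' @param data Numeric n x 3 matrix (n >= 5, nonsingular covariance).
#' @param corrected_skewness Apply the small-sample correction; `NULL`
#'   (default) applies it automatically when n < 20.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return Object of class `"mardia_test"`: `skewness`, `skewness_p`,
#'   `kurtosis` (z), `kurtosis_p`, `normal` (logical verdict), `corrected`,
#'   `n`.
#' @export
mardia_test <- function(data, corrected_skewness = NULL, alpha = 0.05) {
  x <- as.matrix(data)
  p <- ncol(x)
  n <- nrow(x)
  if (p != 3L) stop("data must have 3 columns")
  if (n < 5L) stop("at least 5 observations are required")
  if (is.null(corrected_skewness)) corrected_skewness <- n < 20L
  ctr <- sweep(x, 2L, colMeans(x))
  s <- crossprod(ctr) / n                       # MLE covariance
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (ev[p] <= 1e-12 * ev[1]) stop("singular covariance")
  z <- ctr %*% solve(chol(s))                   # g_ij = z_i . z_j

  # b1 = n^-2 sum_ij (z_i . z_j)^3 via the third-moment tensor:
  # sum_ij (z_i'z_j)^3 = sum_{klm} (sum_i z_ik z_il z_im)^2  -- O(n p^3)
  b1 <- 0
  for (k in seq_len(p)) for (l in seq_len(p)) for (m in seq_len(p)) {
    b1 <- b1 + sum(z[, k] * z[, l] * z[, m])^2
  }
  b1 <- b1 / n^2
  gii <- rowSums(z^2)
  b2 <- mean(gii^2)

  skew_stat <- n * b1 / 6
  if (corrected_skewness) {
    corr <- ((p + 1) * (n + 1) * (n + 3)) / (n * ((n + 1) * (p + 1) - 6))
    skew_stat <- skew_stat * corr
  }
  df_skew <- p * (p + 1) * (p + 2) / 6          # 10 for p = 3
  skew_p <- pchisq(skew_stat, df = df_skew, lower.tail = FALSE)
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  kurt_p <- 2 * pnorm(abs(kurt_z), lower.tail = FALSE)
  structure(
    list(skewness = skew_stat, skewness_p = skew_p,
         kurtosis = kurt_z, kurtosis_p = kurt_p,
         normal = skew_p > alpha && kurt_p > alpha,
         corrected = corrected_skewness, alpha = alpha, n = n),
    class = "mardia_test"
  )
}

#' @export
print.mardia_test <- function(x, ...) {
  cat("Mardia's multivariate normality test (p = 3)\n")
  cat(sprintf("  skewness: chi2 = %.3f%s, p = %.4f\n", x$skewness,
              if (x$corrected) " (small-sample corrected)" else "",
              x$skewness_p))
  cat(sprintf("  kurtosis: z = %.3f, p = %.4f\n", x$kurtosis, x$kurtosis_p))
  cat(sprintf("  verdict : %s at alpha = %.2f (n = %d)\n",
              if (x$normal) "multivariate normal" else "non-normal",
              x$alpha, x$n))
  invisible(x)
}

#' Per-group preprocessing metrics
#'
#' Layman ranges and Mardia p-values for every (species, area) group of a
#' prepared isotope table. Ranges need at least 2 rows, Mardia at least 5;
#' groups below those sizes get NA in the corresponding columns.
#'
#' @param tab Prepared isotope table (after [prepare_isotopes()]).
#' @return `data.frame` with columns `species`, `area`, `n`, `cr`, `nr`,
#'   `sr`, `mardia_skew_p`, `mardia_kurt_p`, `mvn_normal`.
#' @export
group_metrics <- function(tab) {
  groups <- unique(tab[, c("species", "area")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- tab[tab$species == groups$species[i] & tab$area == groups$area[i],
               c("d13C", "d15N", "d34S")]
    n <- nrow(sub)
    rng <- if (n >= 2L) layman_ranges(sub) else c(cr = NA_real_,
                                                  nr = NA_real_,
                                                  sr = NA_real_)
    md <- if (n >= 5L) tryCatch(mardia_test(as.matrix(sub)),
                                error = function(e) NULL) else NULL
    data.frame(
      species = groups$species[i], area = groups$area[i], n = n,
      cr = unname(rng["cr"]), nr = unname(rng["nr"]), sr = unname(rng["sr"]),
      mardia_skew_p = if (is.null(md)) NA_real_ else md$skewness_p,
      mardia_kurt_p = if (is.null(md)) NA_real_ else md$kurtosis_p,
      mvn_normal = if (is.null(md)) NA else md$normal
    )
  })
  do.call(rbind, rows)
}
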