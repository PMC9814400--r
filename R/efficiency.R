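#' Ligand-efficiency panel for a fragment
#'
#' Computes, from the dissociation constant, heavy-atom count and
#' calculated logP of each fragment:
#' \itemize{
#'   \item `pkd = -log10(K_D in M)`
#'   \item `le = 2.303 R T pkd / ha` (kcal/mol per heavy atom;
#'     at T = 298.15 K the prefactor is 1.364)
#'   \item `sile = pkd / ha^0.3` (size-independent ligand efficiency)
#'   \item `lelp = clogp / le` (lipophilicity cost of the efficiency)
#'   \item `lle_at = 0.111 + 1.37 (pkd - clogp) / ha`
#'     (Astex lipophilic ligand efficiency; equals 0.111 when
#'     `pkd == clogp`)
#' }
#' Values are conventionally reported to two decimals (round-half-even).
#'
#' @param kd dissociation constant(s), M (> 0)
#' @param ha heavy-atom count(s) (>= 1)
#' @param clogp calculated logP value(s)
#' @param temperature temperature for the LE prefactor, K
#' @return data frame with columns `pkd`, `le`, `sile`, `lelp`, `lle_at`
#' @examples
#' efficiency_metrics(kd = 147e-6, ha = 17, clogp = 1.80)
#' @export
efficiency_metrics <- function(kd, ha, clogp, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("K_D must be > 0")
  if (any(ha < 1)) stop("heavy-atom count must be >= 1")
  R_kcal <- 1.987204e-3  # kcal mol^-1 K^-1
  pkd <- -log10(kd)
  le <- 2.303 * R_kcal * temperature * pkd / ha
  data.frame(pkd = pkd, le = le, sile = pkd / ha^0.3, lelp = clogp / le,
             lle_at = 0.111 + 1.37 * (pkd - clogp) / ha)
}

#' Summary row of a hit table
#'
#' Panel means in the convention of published hit-table comparisons:
#' the mean pK_D is `-log10` of the arithmetic-mean K_D (not the mean of
#' per-fragment pK_D values); MW, HA and clogP are plain arithmetic
#' means; the four efficiency indices are arithmetic means of the
#' per-fragment values reported to two decimals.
#'
#' @param records data frame with columns `kd_M`, `mw`, `ha`, `clogp`
#' @param temperature temperature for the LE prefactor, K
#' @return one-row data frame with columns `mw`, `ha`, `pkd`, `clogp`,
#'   `le`, `sile`, `lelp`, `lle_at`
#' @export
summarize_hits <- function(records, temperature = 298.15) {
  if (!nrow(records)) stop("empty hit table")
  m <- efficiency_metrics(records$kd_M, records$ha, records$clogp,
                          temperature)
  data.frame(mw = mean(records$mw), ha = mean(records$ha),
             pkd = -log10(mean(records$kd_M)),
             clogp = mean(records$clogp),
             le = mean(round(m$le, 2)), sile = mean(round(m$sile, 2)),
             lelp = mean(round(m$lelp, 2)),
             lle_at = mean(round(m$lle_at, 2)))
}

#' Principal component analysis of molecular descriptors
#'
#' Standardizes the descriptor table (zero mean, unit variance) and
#' decomposes it with [stats::prcomp()]. Constant descriptor columns are
#' dropped with a warning. Explained-variance fractions sum to one.
#'
#' @param x numeric matrix or data frame, fragments x descriptors
#' @param highlight optional row indices (or logical vector) of
#'   fragments whose scores are returned separately as an overlay
#' @return list with `loadings`, `scores`, `var_explained` and
#'   optionally `highlight_scores`
#' @export
descriptor_pca <- function(x, highlight = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 fragments for a PCA")
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("dropping constant descriptor(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  out <- list(loadings = p$rotation, scores = p$x,
              var_explained = p$sdev^2 / sum(p$sdev^2),
              center = p$center, scale = p$scale)
  if (!is.null(highlight))
    out$highlight_scores <- p$x[highlight, , drop = FALSE]
  out
}

#' Fragment hits against the p97 N-domain
#'
#' Affinities (BLI, p97-N and p97-ND1 constructs), descriptors and
#' published two-decimal efficiency values for the ten fragment hits
#' identified against the N-domain of the AAA+ ATPase p97. Used as the
#' reference input for the efficiency panel. Two published cells are
#' internally inconsistent with the remaining columns
#' (`flag_inconsistent`): one molecular weight and two LLE_AT values
#' cannot be reproduced from the printed K_D/HA/clogP under any constant.
#'
#' @return data frame with columns `id`, `kd_M`, `kd_nd1_M`, `mw`, `ha`,
#'   `clogp`, `std_max_pct`, `score_bli`, `le_published`,
#'   `lle_at_published`, `flag_inconsistent`
#' @export
p97_fragments <- function() {
  path <- system.file("extdata", "p97_n_fragment_hits.csv",
                      package = "bliscreen", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$kd_M <- out$kd_uM * 1e-6
  out$kd_nd1_M <- out$kd_nd1_uM * 1e-6
  out
}
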