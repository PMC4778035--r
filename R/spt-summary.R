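#' Summarize mobility records by condition and compartment
#'
#' Pools per-trajectory diffusion coefficients within each condition and
#' compartment (median and 25-75% interquartile range over trajectories),
#' computes per-cell immobile fractions averaged across cells (mean plus
#' standard error, mirroring per-neuron reporting), and tabulates the
#' distribution of log10 D as a normalized histogram and cumulative
#' distribution.
#'
#' @param records data.frame of mobility records with columns `D`,
#'   `compartment`, `mobility` plus grouping columns `condition` and `cell`.
#' @param breaks histogram break points on the log10 D axis.
#' @param dFloor coefficients below this floor are set to it before taking
#'   log10 (immobile tracks can have D = 0).
#' @return list with elements:
#'   * `diffusion`: data.frame `condition`, `compartment`, `median_D`,
#'     `iqr_low`, `iqr_high`, `n`;
#'   * `immobile`: data.frame `condition`, `mean_pct`, `sem_pct`, `n_cells`
#'     (SEM is `NA` for a single cell);
#'   * `per_cell`: per-cell immobile fractions;
#'   * `histogram`: per-condition normalized log10 D histograms (masses sum
#'     to 1) and empirical cumulative fractions;
#'   * `dThreshold`: the immobility threshold carried from the records.
#' @export
summarizeMobility <- function(records,
                              breaks = seq(-6, 1, by = 0.25),
                              dFloor = 1e-6) {
  stopifnot(all(c("D", "compartment", "mobility") %in% names(records)))
  if (nrow(records) == 0L) stop("no mobility records to summarize")
  if (is.null(records$condition)) records$condition <- "all"
  if (is.null(records$cell)) records$cell <- 1L

  ## pooled per-trajectory medians and IQR per condition x compartment
  grp <- interaction(records$condition, records$compartment, drop = TRUE)
  diffusion <- do.call(rbind, lapply(split(records, grp), function(g) {
    q <- stats::quantile(g$D, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = g$condition[1L], compartment = g$compartment[1L],
               median_D = q[2L], iqr_low = q[1L], iqr_high = q[3L],
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(diffusion) <- NULL

  ## per-cell immobile fraction, averaged across cells
  cellGrp <- interaction(records$condition, records$cell, drop = TRUE)
  perCell <- do.call(rbind, lapply(split(records, cellGrp), function(g) {
    data.frame(condition = g$condition[1L], cell = g$cell[1L],
               immobile_fraction = mean(g$mobility == "immobile"),
               n_tracks = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(perCell) <- NULL
  immobile <- do.call(rbind, lapply(split(perCell, perCell$condition),
                                    function(g) {
    data.frame(condition = g$condition[1L],
               mean_pct = 100 * mean(g$immobile_fraction),
               sem_pct = if (nrow(g) >= 2L)
                 100 * stats::sd(g$immobile_fraction) / sqrt(nrow(g))
                 else NA_real_,
               n_cells = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(immobile) <- NULL

  ## log10 D distributions per condition
  histogram <- lapply(split(records, records$condition), function(g) {
    lg <- log10(pmax(g$D, dFloor))
    lg <- pmin(pmax(lg, min(breaks)), max(breaks))
    h <- graphics::hist(lg, breaks = breaks, plot = FALSE)
    list(mids = h$mids, mass = h$counts / sum(h$counts),
         cumulative = cumsum(h$counts) / sum(h$counts))
  })

  list(diffusion = diffusion, immobile = immobile, per_cell = perCell,
       histogram = histogram,
       dThreshold = attr(records, "dThreshold") %||% NA_real_)
}
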