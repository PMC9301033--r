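# Per-generation population analytics: molecular weight of
# pharmacophore-passing compounds and enrichment in high-similarity
# compounds at fixed combined-score thresholds. Note the two denominators:
# mean molecular weight is taken over pharmacophore passers only, while
# enrichment fractions are taken over the whole generation.

#' Molecular weight of a molecule
#'
#' Standard average atomic weights, implicit hydrogens included.
#'
#' @param mol a `mol_record`.
#' @return molecular weight in Dalton.
#' @export
molecular_weight <- function(mol) {
  sum(.atomic_weight(mol$atoms$elem)) +
    sum(implicit_h(mol)) * .ATOMIC_WEIGHTS[["H"]]
}

#' Per-generation population metrics
#'
#' For every generation of an [run_evolution()] result: number of members
#' whose best pose passes the pharmacophore filter, mean molecular weight
#' of the passers (`NA` when there are none), the mean combined
#' shape+electrostatic score, and the fraction of the total population
#' whose combined score reaches each threshold ("exceeds" is read as
#' `>=`).
#'
#' @param run an `evolution_run`.
#' @param model a `pharmacophore_model` used as the pose filter.
#' @param references posed reference ligands for [best_combo()]; may be
#'   omitted when `combos` is supplied.
#' @param thresholds combined-score thresholds; default 0.50 / 0.75 / 1.00.
#' @param tolerance,angle_tolerance passed to [pharm_matches()].
#' @param combos optional precomputed combined scores: a list with one
#'   numeric vector per generation (members in record order).
#' @return a `generation_metrics` data.frame, one row per generation, with
#'   columns `generation`, `n`, `n_pass`, `mean_mw_pass`, `mean_combo` and
#'   `frac_ge_<t>` per threshold.
#' @export
generation_metrics <- function(run, model, references = NULL,
                               thresholds = c(0.50, 0.75, 1.00),
                               tolerance = 1.0, angle_tolerance = 30,
                               combos = NULL) {
  if (is.null(references) && is.null(combos))
    stop("supply either reference poses or precomputed combo scores")
  rows <- list()
  for (gi in seq_along(run$generations)) {
    g <- run$generations[[gi]]
    poses <- attr(g, "poses")
    pass <- logical(nrow(g)); combo <- rep(NA_real_, nrow(g))
    mw <- rep(NA_real_, nrow(g))
    if (!is.null(combos)) combo <- as.numeric(combos[[gi]])
    for (j in seq_len(nrow(g))) {
      p <- poses[[j]]
      if (is.null(p)) next
      mw[j] <- molecular_weight(p)
      pass[j] <- pharm_matches(model, p, tolerance, angle_tolerance)$match
      if (is.null(combos)) {
        p <- assign_gasteiger(p)
        combo[j] <- best_combo(p, references)$et_combo
      }
    }
    row <- data.frame(generation = g$generation[1], n = nrow(g),
                      n_pass = sum(pass),
                      mean_mw_pass = if (any(pass)) mean(mw[pass])
                                     else NA_real_,
                      mean_combo = mean(combo, na.rm = TRUE))
    for (t in thresholds)
      row[[sprintf("frac_ge_%.2f", t)]] <- mean(combo >= t, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("generation_metrics", "data.frame")
  out
}

#' Binned histogram of combined similarity scores
#'
#' Exports the distribution as a table (bin width 0.1 on the 0-2 scale)
#' rather than an image, for testability.
#'
#' @param combos numeric combined scores.
#' @param width bin width.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `density`.
#' @export
combo_histogram <- function(combos, width = 0.1) {
  combos <- combos[!is.na(combos)]
  breaks <- seq(0, max(2, ceiling(max(c(combos, 0)) / width) * width),
                by = width)
  h <- hist(combos, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = head(h$breaks, -1), bin_hi = h$breaks[-1],
             count = h$counts, density = h$density)
}
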