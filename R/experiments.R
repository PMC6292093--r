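# Simulation experiment drivers: accuracy grid over depth x MAF, site-count
# sweep, contamination sensitivity, and unequal depths. Each returns a tidy
# data frame with one row per (cell, rep); medians/quartiles come from
# summarize_experiment(). Every driver is a pure function of its arguments
# and seed.

MAF_WINDOWS <- list(c(0.0, 0.1), c(0.1, 0.2), c(0.2, 0.3),
                    c(0.3, 0.4), c(0.4, 0.5))

posterior_of <- function(result, S) result$posterior[match_vector(result, S)]

run_cell <- function(true_S, L, maf_window, lambda, error_rate,
                     contamination, reps) {
  # runs inside the driver's seeded RNG stream
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(true_S, L = L, maf_window = maf_window, lambda = lambda,
                      error_rate = error_rate, contamination = contamination)
    sim <- simulate_replicates(cfg)
    res <- joint_posterior(sim$dataset)
    top <- res$labels[which.max(res$posterior)]
    out[[r]] <- data.frame(
      rep = r,
      posterior_true = posterior_of(res, true_S),
      argmax = top,
      recovered = identical(top, format_source_vector(true_S)))
  }
  do.call(rbind, out)
}

cell_frame <- function(true_S, lambda, maf_window, L, rows) {
  cbind(data.frame(true_S = format_source_vector(true_S),
                   lambda = paste(lambda, collapse = ","),
                   maf_min = maf_window[1], maf_max = maf_window[2], L = L),
        rows)
}

#' Accuracy grid: median true-partition posterior over depth x MAF
#'
#' Full-factorial simulate-and-infer experiment: for each (source vector,
#' mean depth, MAF window) cell, simulates `reps` independent datasets of
#' `L` sites and records the posterior assigned to the true source vector
#' and whether it was the posterior argmax.
#'
#' @param k Number of replicates; sets the default source vectors to one
#'   representative per partition shape ([source_vector_classes()]).
#' @param true_vectors Optional list of source vectors to simulate instead.
#' @param depth_grid Mean read depths; default `c(1, 2, 3, 6, 15)`.
#' @param maf_windows List of length-2 MAF windows; default the five decile
#'   windows `(0,0.1] .. (0.4,0.5]`.
#' @param L Sites per dataset (default 1000).
#' @param reps Simulated datasets per cell.
#' @param error_rate Per-read error rate (default 0.01).
#' @param seed Integer seed; the full table is reproducible from it.
#' @return Tidy data frame: one row per (cell, rep) with `true_S`, `lambda`,
#'   `maf_min`, `maf_max`, `L`, `rep`, `posterior_true`, `argmax`,
#'   `recovered`.
#' @export
run_accuracy_grid <- function(k = 3, true_vectors = NULL,
                              depth_grid = c(1, 2, 3, 6, 15),
                              maf_windows = MAF_WINDOWS,
                              L = 1000, reps = 100, error_rate = 0.01,
                              seed = 1L) {
  if (is.null(true_vectors)) true_vectors <- source_vector_classes(k)
  withr::with_seed(seed, {
    out <- list()
    for (S in true_vectors) {
      for (lam in depth_grid) {
        for (w in maf_windows) {
          rows <- run_cell(S, L, w, lam, error_rate, NULL, reps)
          out[[length(out) + 1L]] <- cell_frame(S, lam, w, L, rows)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Site-count sweep at a fixed MAF window
#'
#' Repeats the accuracy experiment while varying the number of analyzed
#' sites `L`, by default over the paper-scale grid 50..5000 in the
#' `(0.2, 0.3]` window where accuracy is depth-limited.
#'
#' @param true_vectors List of source vectors; default `(1,2,1)` and
#'   `(1,2,3)`.
#' @param L_values Site counts; default
#'   `c(50, 100, 250, 500, 1000, 2000, 5000)`.
#' @param depth_grid Mean read depths; default `c(1, 2, 3, 6, 15)`.
#' @param maf_window Single MAF window; default `c(0.2, 0.3)`.
#' @inheritParams run_accuracy_grid
#' @return Tidy data frame as in [run_accuracy_grid()].
#' @export
run_L_sweep <- function(true_vectors = list(c(1L, 2L, 1L), c(1L, 2L, 3L)),
                        L_values = c(50, 100, 250, 500, 1000, 2000, 5000),
                        depth_grid = c(1, 2, 3, 6, 15),
                        maf_window = c(0.2, 0.3),
                        reps = 100, error_rate = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    out <- list()
    for (S in true_vectors) {
      for (L in L_values) {
        for (lam in depth_grid) {
          rows <- run_cell(S, L, maf_window, lam, error_rate, NULL, reps)
          out[[length(out) + 1L]] <- cell_frame(S, lam, maf_window, L, rows)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Contamination sensitivity of the no-error call
#'
#' Simulates two true replicates (`S = (1,1)`), contaminates a fraction `p`
#' of sample 2's sites with an independently drawn genotype source, and
#' records how much posterior mass remains on `(1,1)`. Sensitivity to
#' contamination grows with read depth: deep data distinguish biological
#' difference from sampling noise.
#'
#' @param p_values Contaminated-site fractions; default
#'   `c(0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @param depth_grid Mean read depths; default `c(1, 2, 3, 6, 15)`.
#' @param maf_window MAF window; default `c(0.4, 0.5)`.
#' @param contaminated_sample Which sample is contaminated (default 2).
#' @inheritParams run_accuracy_grid
#' @return Tidy data frame with an extra `p` column; `posterior_true` is
#'   the posterior of `(1,1)`.
#' @export
run_sensitivity <- function(p_values = c(0.1, 0.2, 0.3, 0.4, 0.5),
                            depth_grid = c(1, 2, 3, 6, 15),
                            L = 1000, maf_window = c(0.4, 0.5),
                            contaminated_sample = 2L,
                            reps = 100, error_rate = 0.01, seed = 1L) {
  true_S <- c(1L, 1L)
  withr::with_seed(seed, {
    out <- list()
    for (p in p_values) {
      for (lam in depth_grid) {
        cont <- list(sample = contaminated_sample, p = p)
        rows <- run_cell(true_S, L, maf_window, lam, error_rate, cont, reps)
        out[[length(out) + 1L]] <-
          cbind(cell_frame(true_S, lam, maf_window, L, rows), p = p)
      }
    }
    do.call(rbind, out)
  })
}

#' Accuracy when mean read depths differ between samples
#'
#' Keeps all samples but the last at a fixed mean depth (default 1x) and
#' varies the last sample's depth, mirroring the design where sample d = 2
#' of `(1,1)`/`(1,2)` or d = 3 of `(1,2,1)` is the deep one.
#'
#' @param true_vectors List of source vectors; default `(1,1)`, `(1,2)`,
#'   `(1,2,1)`.
#' @param varied_depths Depths for the varied (last) sample; default
#'   `c(1, 2, 4, 6, 12)`.
#' @param fixed_depth Depth of the remaining samples; default 1.
#' @param maf_windows List of MAF windows; default the five decile windows.
#' @inheritParams run_accuracy_grid
#' @return Tidy data frame as in [run_accuracy_grid()]; the `lambda` column
#'   holds the per-sample depth vector, comma-joined.
#' @export
run_unequal_depths <- function(true_vectors = list(c(1L, 1L), c(1L, 2L),
                                                   c(1L, 2L, 1L)),
                               varied_depths = c(1, 2, 4, 6, 12),
                               fixed_depth = 1,
                               maf_windows = MAF_WINDOWS,
                               L = 1000, reps = 100, error_rate = 0.01,
                               seed = 1L) {
  withr::with_seed(seed, {
    out <- list()
    for (S in true_vectors) {
      k <- length(S)
      for (lam in varied_depths) {
        lambda <- c(rep(fixed_depth, k - 1L), lam)
        for (w in maf_windows) {
          rows <- run_cell(S, L, w, lambda, error_rate, NULL, reps)
          out[[length(out) + 1L]] <- cell_frame(S, lambda, w, L, rows)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Summarize an experiment table per cell
#'
#' Collapses the per-rep rows of any `run_*` driver to per-cell summaries:
#' median and quartiles of the true-partition posterior and the fraction of
#' reps where the truth was the posterior argmax.
#'
#' @param df Output of a `run_*` driver.
#' @return Data frame with one row per cell and columns `n_reps`,
#'   `median_posterior`, `q25`, `q75`, `recovery_rate`.
#' @export
summarize_experiment <- function(df) {
  by_cols <- intersect(c("true_S", "lambda", "maf_min", "maf_max", "L", "p"),
                       names(df))
  keys <- df[by_cols]
  split_idx <- split(seq_len(nrow(df)), keys, drop = TRUE)
  rows <- lapply(split_idx, function(idx) {
    cell <- df[idx, , drop = FALSE]
    q <- stats::quantile(cell$posterior_true, c(0.25, 0.5, 0.75), names = FALSE)
    cbind(cell[1L, by_cols, drop = FALSE],
          data.frame(n_reps = nrow(cell), median_posterior = q[2],
                     q25 = q[1], q75 = q[3],
                     recovery_rate = mean(cell$recovered)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
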