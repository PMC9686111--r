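# Phase-confidence estimation. A minority of runs phase poorly genome-wide
# (down to 50%, i.e. the two parents' alleles evenly mixed); run-level
# features of the IBD data and of the clustering predict the global error
# well enough to flag them.

#' Extract confidence features from a phasing run
#'
#' Run-level summaries of the IBD evidence and the clustering, used to
#' predict genome-wide phase error. Ratios with empty denominators are
#' emitted as `cap` (or 0 when there is no data at all); counts enter as
#' `log(1 + n)`.
#'
#' @param fit An [ibd_phase()] object.
#' @param cap Value substituted for ratios with an empty denominator.
#' @return Named list of 15 numeric features: proportion of database
#'   individuals with fragments on both global sides within the largest
#'   supercluster; proportion of segments split across sides; number of
#'   close family members not sharing IBD with all other close family;
#'   log counts of IBD individuals and of largest-supercluster segments;
#'   missing close-family edges; genome cM coverage by >= 1/2/5/10/20
#'   segments; single- vs multi-segment individual ratio; proportion of
#'   segments in the largest supercluster; and the mean and median
#'   majority/minority side cM ratio per individual.
#' @export
extract_features <- function(fit, cap = 100) {
  seg <- fit$segments
  fr <- fit$fragments
  panel <- fit$panel
  gcm <- genome_cm(panel)

  n_ind <- length(unique(seg$other_id))
  seg_per_ind <- table(seg$other_id)
  n_single <- sum(seg_per_ind == 1L)
  n_multi <- sum(seg_per_ind > 1L)
  single_vs_multi <- if (n_ind == 0L) 0 else if (n_multi == 0L) cap else n_single / n_multi

  # coverage: fraction of genome cM overlapped by >= k segments
  coverage_at <- function(k) {
    if (!nrow(seg)) return(0)
    cov <- 0
    for (cc in unique(panel$chrom)) {
      s <- seg[seg$chrom == cc, , drop = FALSE]
      if (!nrow(s)) next
      ev <- data.frame(pos = c(panel$cm[s$start], panel$cm[s$end]),
                       d = rep(c(1, -1), each = nrow(s)))
      ev <- ev[order(ev$pos, -ev$d), ]
      depth <- cumsum(ev$d)
      len <- diff(ev$pos)
      cov <- cov + sum(len[depth[-length(depth)] >= k])
    }
    cov / gcm
  }

  in_largest <- if (nrow(fr)) fr$component == fit$largest_sc else logical(0)
  frl <- fr[in_largest, , drop = FALSE]
  both_sides_frac <- if (nrow(frl)) {
    per <- tapply(frl$global_side, frl$other_id, function(s) length(unique(s)) > 1L)
    mean(per)
  } else 0
  split_frac <- if (nrow(fr)) {
    per <- tapply(fr$global_side, fr$seg_row, function(s) length(unique(s)) > 1L)
    mean(per)
  } else 0
  n_seg_largest <- length(unique(frl$seg_row))
  frac_seg_largest <- if (nrow(seg)) n_seg_largest / nrow(seg) else 0

  nodes <- fit$family$graph$nodes
  edges <- fit$family$graph$edges
  if (length(nodes) >= 2L) {
    deg <- table(factor(c(edges$a, edges$b), levels = nodes))
    n_inconsistent <- sum(deg < length(nodes) - 1L)
    n_missing_edges <- length(nodes) * (length(nodes) - 1L) / 2L - nrow(edges)
  } else {
    n_inconsistent <- 0L; n_missing_edges <- 0L
  }

  mm_ratio <- if (nrow(fr)) {
    per <- tapply(seq_len(nrow(fr)), fr$other_id, function(ix) {
      cmA <- sum(fr$cm[ix][fr$global_side[ix] == 1L])
      cmB <- sum(fr$cm[ix][fr$global_side[ix] == 2L])
      lo <- min(cmA, cmB); hi <- max(cmA, cmB)
      if (lo == 0) cap else hi / lo
    })
    as.numeric(per)
  } else numeric(0)

  list(frac_both_sides_largest_sc = both_sides_frac,
       frac_split_segments = split_frac,
       n_inconsistent_close_family = as.numeric(n_inconsistent),
       log_n_ibd_individuals = log1p(n_ind),
       log_n_segments_largest_sc = log1p(n_seg_largest),
       n_missing_family_edges = as.numeric(n_missing_edges),
       genome_coverage_1x = coverage_at(1), genome_coverage_2x = coverage_at(2),
       genome_coverage_5x = coverage_at(5), genome_coverage_10x = coverage_at(10),
       genome_coverage_20x = coverage_at(20),
       single_vs_multi_ratio = single_vs_multi,
       frac_segments_largest_sc = frac_seg_largest,
       majority_minority_ratio_mean = if (length(mm_ratio)) mean(mm_ratio) else 0,
       majority_minority_ratio_median = if (length(mm_ratio)) stats::median(mm_ratio) else 0)
}

#' Fit the phase-error regression model
#'
#' Random-forest regression of observed genome-wide phase error (as a
#' fraction in `[0, 1]`) on run-level confidence features. The regressor is
#' pluggable via `engine`.
#'
#' @param features data.frame (or list of named lists) of
#'   [extract_features()] rows.
#' @param errors Observed global phase error per run, fraction in `[0, 1]`.
#' @param engine Function `(x, y, ...) -> model` with a `predict` method.
#'   The default (`NULL`) fits [randomForest::randomForest] with 1000 trees
#'   and half the features tried per split, a configuration with enough
#'   per-split attention to single strong predictors at this feature count.
#' @param ... Passed to the engine.
#' @return Object of class `"phase_error_model"`.
#' @export
fit_error_model <- function(features, errors, engine = NULL, ...) {
  x <- if (is.data.frame(features)) features else
    as.data.frame(do.call(rbind, lapply(features, unlist)))
  x <- as.data.frame(lapply(x, as.numeric))
  if (nrow(x) != length(errors)) stop("feature/label length mismatch")
  model <- if (is.null(engine)) {
    randomForest::randomForest(x = x, y = as.numeric(errors), ntree = 1000,
                               mtry = max(1L, floor(ncol(x) / 2)), ...)
  } else engine(x = x, y = as.numeric(errors), ...)
  structure(list(model = model, feature_names = names(x)),
            class = "phase_error_model")
}

#' @export
predict.phase_error_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  unname(stats::predict(object$model, newdata = newdata, ...))
}

#' @export
print.phase_error_model <- function(x, ...) {
  cat("Phase-error regression model (", class(x$model)[1L], ")\n", sep = "")
  imp <- tryCatch(randomForest::importance(x$model), error = function(e) NULL)
  if (!is.null(imp)) {
    ord <- order(imp[, 1L], decreasing = TRUE)
    cat("Feature importance:\n")
    print(round(imp[ord, , drop = FALSE], 3))
  }
  invisible(x)
}

#' Conservative fallback for low-confidence runs
#'
#' When the predicted genome-wide error exceeds 20% (strictly), the
#' confident labelling is restricted from the largest supercluster to the
#' largest single subcluster, expressing confidence over a smaller portion
#' of the genome. The genome-wide phase itself is unchanged.
#'
#' @param prediction Predicted error (fraction).
#' @param fit An [ibd_phase()] object.
#' @param threshold Fallback threshold (default 0.20).
#' @return List: `fallback` (logical), `scope` (`"largest_supercluster"` or
#'   `"largest_subcluster"`), `confident_fragments` (row indices into
#'   `fit$fragments`).
#' @export
apply_confidence_fallback <- function(prediction, fit, threshold = 0.20) {
  fr <- fit$fragments
  if (prediction > threshold) {
    sub <- if (nrow(fr)) {
      tb <- table(fr$subcluster)
      as.integer(names(which.max(tb)))
    } else NA_integer_
    list(fallback = TRUE, scope = "largest_subcluster",
         confident_fragments = which(fr$subcluster == sub))
  } else {
    list(fallback = FALSE, scope = "largest_supercluster",
         confident_fragments = which(fr$component == fit$largest_sc & !fr$pruned))
  }
}
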