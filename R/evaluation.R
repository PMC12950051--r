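#' Jaccard index of two binary masks
#'
#' Intersection over union `|A n B| / |A u B|`. When both masks are empty
#' the index is defined as 1 (perfect agreement on the absence of a
#' lesion); this convention is documented rather than universal.
#'
#' @param a,b binary arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- as.logical(vg_values(a)); b <- as.logical(vg_values(b))
  if (length(a) != length(b))
    stop("masks must share a shape")
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Dice coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; both-empty convention 1. Algebraically
#' `D = 2J / (1 + J)` for the Jaccard index `J` of the same masks.
#'
#' @inheritParams jaccard_index
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(vg_values(a)); b <- as.logical(vg_values(b))
  if (length(a) != length(b))
    stop("masks must share a shape")
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Patient-level fold assignment
#'
#' Seeded random permutation followed by round-robin assignment: folds are
#' mutually exclusive, jointly exhaustive, and their sizes differ by at most
#' one (e.g. 151 patients at k = 5 give sizes 31, 30, 30, 30, 30).
#'
#' @param patient_ids character vector of unique ids.
#' @param k number of folds.
#' @param seed permutation seed.
#' @return A `fold_assignment`: list with `assignment` (named integer vector
#'   of fold indices 1..k), `k`, `seed`.
#' @export
make_folds <- function(patient_ids, k = 5L, seed = 1L) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  if (k > n) stop("config error: k exceeds the number of patients")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  perm <- sample(patient_ids)
  fold <- rep_len(seq_len(k), n)
  assignment <- setNames(fold, perm)[patient_ids]
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Patient-level cross-validation over model variants
#'
#' For each fold and each variant, trains on the complement and scores every
#' held-out patient once (Jaccard and Dice of the thresholded prediction
#' against ground truth). One fold assignment is shared by all variants so
#' the per-patient scores are paired across variants.
#'
#' @param studies list of prepared studies; each needs `patient_id`,
#'   `lesion_label`, model input arrays (`pre`/`early`/`diff`) and binary
#'   `mask`.
#' @param variants character vector of model variants to compare.
#' @param model_template a [model_config()]; its `variant` field is replaced
#'   per run, everything else (widths, input shape) is shared.
#' @param train_cfg a [train_config()].
#' @param k folds (default 5).
#' @param seed master seed; fans out deterministically to the fold split and
#'   to each fold-variant training run.
#' @param folds optional precomputed [make_folds()] result.
#' @param test_folds optional subset of fold indices to hold out and score
#'   (`NULL` runs every fold, the full rotation); a single index gives a
#'   plain train/test split at the same patient-level grouping.
#' @param threshold probability threshold for [binarize()].
#' @param trainer optional override returning a predictor: called as
#'   `trainer(variant, train_studies, seed)` and must return
#'   `function(study) -> probability array`. Used for plumbing tests with
#'   stub models; `NULL` trains the real network.
#' @param verbose log fold progress.
#' @return Data frame of case scores: `patient_id`, `variant`, `fold`,
#'   `label`, `jaccard`, `dice`.
#' @export
cross_validate <- function(studies, variants, model_template,
                           train_cfg = train_config(), k = 5L, seed = 1L,
                           folds = NULL, test_folds = NULL, threshold = 0.5,
                           trainer = NULL, verbose = FALSE) {
  ids <- vapply(studies, function(s) s$patient_id, character(1))
  names(studies) <- ids
  if (is.null(folds)) folds <- make_folds(ids, k = k, seed = seed)
  k <- folds$k
  run_seeds <- matrix(derive_seeds(seed + 1L, k * length(variants)),
                      nrow = k)
  if (is.null(trainer))
    trainer <- function(variant, train_studies, tseed) {
      cfg <- model_template
      cfg$variant <- variant
      model <- nme_model(cfg, seed = tseed)
      tc <- train_cfg
      tc$seed <- tseed
      fit <- train_model(train_studies, model, tc)
      function(study) model_forward(fit$model, study)
    }
  if (is.null(test_folds)) test_folds <- seq_len(k)
  rows <- list()
  for (f in test_folds) {
    test_ids <- ids[folds$assignment[ids] == f]
    train_ids <- setdiff(ids, test_ids)
    for (vi in seq_along(variants)) {
      v <- variants[vi]
      if (verbose)
        message(sprintf("fold %d/%d, variant %s: training on %d patients",
                        f, k, v, length(train_ids)))
      predict_fn <- trainer(v, studies[train_ids], run_seeds[f, vi])
      for (pid in test_ids) {
        s <- studies[[pid]]
        prob <- predict_fn(s)
        pred <- binarize(prob, threshold)
        truth <- as.logical(vg_values(s$mask))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, variant = v, fold = f,
          label = s$lesion_label,
          jaccard = jaccard_index(pred, truth),
          dice = dice_coefficient(pred, truth),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate case scores into a comparison table
#'
#' Mean and standard deviation (n - 1 denominator, the convention behind
#' "mean +/- SD" reporting) of Jaccard and Dice per variant for all cases
#' and for the benign / malignant subgroups. Empty subgroups are omitted
#' with a warning.
#'
#' @param scores data frame from [cross_validate()].
#' @return Data frame with `variant`, `subgroup`, `metric`, `mean`, `sd`,
#'   `n`.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(nrow(scores) > 0)
  subgroups <- list(all = rep(TRUE, nrow(scores)),
                    benign = scores$label == "benign",
                    malignant = scores$label == "malignant")
  rows <- list()
  for (sg in names(subgroups)) {
    sub <- scores[subgroups[[sg]], , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("subgroup '%s' is empty; omitted", sg))
      next
    }
    for (v in unique(scores$variant)) {
      sv <- sub[sub$variant == v, , drop = FALSE]
      if (nrow(sv) == 0L) next
      for (m in c("jaccard", "dice")) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, subgroup = sg, metric = m,
          mean = mean(sv[[m]]),
          sd = if (nrow(sv) > 1L) sd(sv[[m]]) else NA_real_,
          n = nrow(sv), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Two-sided Wilcoxon signed-rank test: zero differences dropped, mid-ranks
# for ties, exact null distribution for n <= 25 (computed by convolving the
# rank generating function, so tied mid-ranks are handled exactly),
# otherwise normal approximation with tie and continuity corrections.
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p = 1, n = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # null distribution of 2W (integer support even with mid-ranks)
    r2 <- as.integer(round(2 * r))
    dist <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    W2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(W2 + 1L)])
    p_ge <- sum(dist[(W2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p = p, n = n)
}

#' Paired Wilcoxon signed-rank tests with Holm correction
#'
#' Tests each non-reference variant against the reference variant on the
#' per-patient paired metric values, then applies the Holm step-down
#' adjustment across that family of comparisons (separately per metric).
#'
#' @param scores data frame from [cross_validate()].
#' @param reference reference variant (the proposed model by default).
#' @param metrics which metrics to test.
#' @return Data frame with `variant`, `metric`, `statistic`, `n`, `p_raw`,
#'   `p_holm`.
#' @export
wilcoxon_holm <- function(scores, reference = "dual_enc_temporal_attention",
                          metrics = c("jaccard", "dice")) {
  variants <- setdiff(unique(scores$variant), reference)
  if (!reference %in% scores$variant)
    stop("reference variant absent from the scores")
  out <- list()
  for (m in metrics) {
    ref <- scores[scores$variant == reference, c("patient_id", m)]
    rows <- lapply(variants, function(v) {
      sv <- scores[scores$variant == v, c("patient_id", m)]
      merged <- merge(ref, sv, by = "patient_id", suffixes = c(".ref", ".v"))
      if (nrow(merged) != nrow(ref))
        stop(sprintf("pairing failure: variant '%s' misses patients", v))
      wt <- wilcoxon_signed_rank(merged[[paste0(m, ".ref")]],
                                 merged[[paste0(m, ".v")]])
      data.frame(variant = v, metric = m, statistic = wt$statistic,
                 n = wt$n, p_raw = wt$p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_holm <- p.adjust(tab$p_raw, method = "holm")
    out[[m]] <- tab
  }
  do.call(rbind, out)
}

#' Write case scores as CSV
#' @param scores data frame of case scores.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
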