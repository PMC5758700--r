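# Pure maximin Kennard-Stone: returns `n_train` row indices. The two most
# distant samples seed the set; each step adds the sample whose minimum
# distance to the selected set is largest. Ties break to the lowest index.
kennard_stone_indices <- function(X, n_train) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- sort(far[1, ])
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

#' Kennard-Stone training/validation split
#'
#' Classic maximin selection on Euclidean distance: the two most distant
#' samples seed the training set, then each step adds the sample whose
#' minimum distance to the current training set is largest. The validation
#' set is the remainder (size `round(n * validation_fraction)`). A post-hoc
#' repair swaps nearest cross-set pairs until every region class appears in
#' both sets, with at least two training samples per class (one when a class
#' has only two samples overall) so that discriminant modeling and
#' leave-one-out validation stay feasible. The algorithm is deterministic;
#' ties break to the lowest sample index.
#'
#' @param s A [spectra_set()] with at least 6 samples and at least 2 samples
#'   per region class present.
#' @param validation_fraction Fraction held out (default 1/3, the 2:1 split).
#' @return The same [spectra_set()] with `meta$set_membership` filled with
#'   `"training"` / `"validation"`.
#' @export
kennard_stone_split <- function(s, validation_fraction = 1/3) {
  X <- s$absorbance
  n <- nrow(X)
  if (n < 6) abort("Need at least 6 samples.", class = "nirselect_split_error")
  classes <- s$meta$region_class
  tab <- table(classes)
  if (any(tab < 2)) {
    abort("Every region class present needs at least 2 samples.",
          class = "nirselect_split_error")
  }
  n_val <- round(n * validation_fraction)
  n_train <- n - n_val
  D <- as.matrix(dist(X))
  in_train <- seq_len(n) %in% kennard_stone_indices(X, n_train)

  totals <- table(factor(classes, levels = sort(unique(classes))))
  need <- function(cls, train) {
    if (train) min(2, totals[[as.character(cls)]] - 1) else 1L
  }
  count <- function(cls, train) sum(classes[in_train == train] == cls)
  deficits <- function() {
    out <- list()
    for (cls in sort(unique(classes))) {
      if (count(cls, TRUE) < need(cls, TRUE)) out <- c(out, list(c(cls, 1)))
      if (count(cls, FALSE) < need(cls, FALSE)) out <- c(out, list(c(cls, 0)))
    }
    out
  }
  guard <- 0
  repeat {
    defs <- deficits()
    if (length(defs) == 0) break
    guard <- guard + 1
    if (guard > 4 * n) abort("Cannot repair class coverage of the split.",
                             class = "nirselect_split_error")
    cls <- defs[[1]][1]; to_train <- defs[[1]][2] == 1
    # a donor moves into the deficient side; the source side must keep its
    # own minimum for that class
    donors <- if (count(cls, !to_train) > need(cls, !to_train)) {
      which((in_train != to_train) & classes == cls)
    } else integer(0)
    # the swap partner leaves the deficient side; its class must stay above
    # its minimum there
    partners <- which((in_train == to_train) & classes != cls)
    partners <- partners[vapply(partners, function(i)
      count(classes[i], to_train) > need(classes[i], to_train), logical(1))]
    if (length(donors) == 0 || length(partners) == 0) {
      abort("Cannot repair class coverage of the split.",
            class = "nirselect_split_error")
    }
    dd <- D[donors, partners, drop = FALSE]
    best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    d_i <- donors[best[1]]; p_i <- partners[best[2]]
    in_train[d_i] <- to_train
    in_train[p_i] <- !to_train
  }
  s$meta$set_membership <- ifelse(in_train, "training", "validation")
  s
}

#' Extract the training or validation subset
#'
#' @param s A split [spectra_set()].
#' @param which `"training"` or `"validation"`.
#' @return A [spectra_set()] restricted to that set.
#' @export
subset_split <- function(s, which = c("training", "validation")) {
  which <- match.arg(which)
  idx <- s$meta$set_membership == which
  if (!any(idx)) abort(sprintf("No samples with set_membership '%s'.", which),
                       class = "nirselect_split_error")
  subset_samples(s, idx)
}

# minimum pairwise distance of a subset (the Kennard-Stone maximin criterion)
min_pairwise_distance <- function(X, idx) {
  min(dist(X[idx, , drop = FALSE]))
}
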