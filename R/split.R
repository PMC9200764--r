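#' Patient-level k-fold split plan
#'
#' Partitions the cohort's patients into `k` disjoint test folds covering
#' every patient exactly once; within each fold the remaining patients are
#' split into train and validation sets by the given fractions. Splits are
#' always by patient, never by slide, so all slides of a patient land on the
#' same side of every split.
#'
#' @param x a [cohort].
#' @param k number of folds (>= 2).
#' @param fractions length-2 numeric `(train, val)` giving the relative
#'   train/validation proportions; the defaults reproduce a 70/10/20 design
#'   at `k = 5` (and approximately at `k = 4`).
#' @param seed integer; the plan is deterministic given the seed.
#' @return object of class `split_plan`: list with `folds` (each a list of
#'   `train`, `val`, `test` character id vectors), `k`, `seed`.
#' @export
make_split_plan <- function(x, k = 5, fractions = c(train = 0.7, val = 0.1), seed = 1) {
  stopifnot(inherits(x, "cohort"))
  ids <- x$patients$patient_id
  n <- length(ids)
  if (k < 2) stop_validation("k must be >= 2")
  if (k > n) stop_validation("k = %d exceeds the number of patients (%d)", k, n)
  if (any(fractions <= 0) || sum(fractions) >= 1) {
    stop_validation("fractions must be positive with train + val < 1")
  }
  val_share <- fractions[[2L]] / sum(fractions)

  folds <- with_local_seed(seed, {
    perm <- sample(ids)
    # evenly sized contiguous chunks of the permutation
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    test_sets <- split(perm, rep(seq_len(k), times = sizes))
    lapply(seq_len(k), function(i) {
      test <- test_sets[[i]]
      rest <- sample(setdiff(perm, test))
      n_val <- max(1L, round(length(rest) * val_share))
      list(train = sort(rest[-seq_len(n_val)]),
           val = sort(rest[seq_len(n_val)]),
           test = sort(test))
    })
  })
  structure(list(folds = folds, k = k, seed = seed), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) lengths(f), integer(3))
  cat(sprintf("<split_plan> k = %d, seed = %d; fold sizes (train/val/test):\n", x$k, x$seed))
  cat(paste(apply(sizes, 2, paste, collapse = "/"), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / read a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @return `path` (write) or the `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(k = plan$k, seed = plan$seed, folds = plan$folds),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(x$k), function(i) {
    f <- if (is.data.frame(x$folds)) as.list(x$folds[i, ]) else x$folds[[i]]
    list(train = as.character(unlist(f$train)),
         val = as.character(unlist(f$val)),
         test = as.character(unlist(f$test)))
  })
  structure(list(folds = folds, k = x$k, seed = x$seed), class = "split_plan")
}
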