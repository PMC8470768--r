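#' Validation accuracy of a fused classifier subset
#'
#' Fuses the subset's score matrices by the normalized sum rule and measures
#' argmax accuracy against the labels (ties resolved toward the first class
#' column). The fusion is commutative, so subset order is irrelevant.
#'
#' @param subset unit ids (names or indices into `score_matrices`).
#' @param score_matrices named list of aligned `samples x classes` score
#'   matrices, one per candidate unit.
#' @param labels true labels of the validation samples.
#' @return accuracy in `[0, 1]`.
#' @export
evaluate_subset <- function(subset, score_matrices, labels) {
  if (!length(subset)) stop("cannot evaluate an empty subset")
  fused <- sum_rule_fuse(score_matrices[subset])
  mean(score_to_pred(fused) == as.character(labels))
}

#' Sequential forward floating selection of classifier subsets
#'
#' Greedy forward inclusion of the candidate giving the largest fused
#' validation accuracy, with a floating backtracking step after every
#' inclusion: the member whose removal yields the best accuracy is dropped
#' whenever that accuracy strictly improves the best value recorded at the
#' reduced subset size (strict improvement prevents cycles; a hard cap of
#' `10 * |pool|` sweeps guards termination). The search explores subset sizes
#' up to the full pool and returns the best subset of size `target_X`
#' encountered anywhere along the way. Candidates are scanned in unit-id
#' order and replacements accepted only on strict improvement, so ties break
#' toward the lower unit id and the whole procedure is deterministic.
#'
#' @param pool candidate unit ids (character or integer).
#' @param evaluate function mapping a subset of ids to a validation accuracy;
#'   must be deterministic.
#' @param target_X final subset size (`<= |pool|`).
#' @return the selected ids, with attributes `"accuracy"` (their fused
#'   validation accuracy), `"history"` (best accuracy per subset size) and
#'   `"trace"` (data.frame of accepted add/remove steps).
#' @export
sffs_select <- function(pool, evaluate, target_X) {
  pool <- as.vector(pool)
  if (target_X > length(pool)) stop("target size exceeds pool size")
  if (target_X < 1L) stop("target size must be positive")
  pool <- pool[order(pool)]                  # id order drives tie-breaking
  p <- length(pool)
  best_acc <- -Inf
  best_subset <- pool[seq_len(target_X)]
  best_at <- rep(-Inf, p)
  record <- function(subset, acc) {
    s <- length(subset)
    if (acc > best_at[s]) best_at[s] <<- acc
    if (s == target_X && acc > best_acc) {
      best_acc <<- acc
      best_subset <<- subset
    }
  }
  ev <- function(subset) {
    acc <- evaluate(subset)
    record(subset, acc)
    acc
  }
  selected <- pool[0]
  trace <- list(); step <- 0L
  note <- function(action, id, acc) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, action = action,
                                 unit = as.character(id), accuracy = acc,
                                 size = length(selected),
                                 stringsAsFactors = FALSE)
  }
  sweeps <- 0L
  while (length(selected) < p && sweeps < 10L * p) {
    sweeps <- sweeps + 1L
    # forward: best addition, first (lowest-id) maximum wins
    cand <- setdiff(pool, selected)
    accs <- vapply(cand, function(id) ev(c(selected, id)), numeric(1))
    selected <- c(selected, cand[which.max(accs)])
    note("add", cand[which.max(accs)], max(accs))
    # floating: conditional exclusion, accepted only when the reduced subset
    # strictly improves on the best previously known at that size
    while (length(selected) > 2L && sweeps < 10L * p) {
      prev_best <- best_at[length(selected) - 1L]
      raccs <- vapply(seq_along(selected),
                      function(i) ev(selected[-i]), numeric(1))
      best_i <- which.max(raccs)
      if (raccs[best_i] > prev_best) {
        removed <- selected[best_i]
        selected <- selected[-best_i]
        note("remove", removed, raccs[best_i])
        sweeps <- sweeps + 1L
      } else break
    }
  }
  # backtracking replacement: swap members of the incumbent subset for
  # better-performing pool units until no single swap strictly improves
  repeat {
    improved <- FALSE
    outside <- setdiff(pool, best_subset)
    if (!length(outside) || length(best_subset) == 0L) break
    cur <- best_acc
    for (i in seq_along(best_subset)) {
      for (u in outside) {
        trial <- best_subset; trial[i] <- u
        acc <- ev(trial)
        if (acc > cur) improved <- TRUE
      }
    }
    if (!improved) break
    note("replace", paste(best_subset, collapse = "+"), best_acc)
  }
  structure(best_subset, accuracy = best_acc,
            history = best_at[seq_len(p)],
            trace = do.call(rbind, trace))
}
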