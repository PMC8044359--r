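#' Build repeated k-fold cross-validation plans with forced training lines
#'
#' Each run is an independent random partition of the non-forced lines into
#' `k` folds whose sizes differ by at most one; `forcedTrain` lines (e.g.
#' lines shared between panels) never appear in a test fold.
#'
#' @param lineIds lines to partition.
#' @param k folds per run.
#' @param nRuns resampling runs.
#' @param forcedTrain ids always kept in training.
#' @param seed integer seed; plans are reproducible.
#' @return list of class `FoldPlan`: one element per run with `fold`
#'   (named integer vector over non-forced lines) and `forcedTrain`.
#' @export
makeFoldPlan <- function(lineIds, k = 5, nRuns = 50,
                         forcedTrain = character(0), seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (!all(forcedTrain %in% lineIds))
    stop("forcedTrain ids not in line set: ",
         paste(head(setdiff(forcedTrain, lineIds), 5), collapse = ", "))
  free <- setdiff(lineIds, forcedTrain)
  if (length(free) < k) stop("fewer non-forced lines than folds")
  plans <- withSeed(seed, lapply(seq_len(nRuns), function(run) {
    fold <- sample(rep(seq_len(k), length.out = length(free)))
    list(run = run, fold = setNames(fold, free), forcedTrain = forcedTrain)
  }))
  structure(plans, class = "FoldPlan")
}

#' Run repeated cross-validation for several prediction methods
#'
#' For every run and fold, each method's factory is called with the test
#' line ids (the method must mask those phenotypes internally, fit, and
#' return a named GEBV vector covering them); accuracy is the Pearson
#' correlation between GEBV and the observed values of the test lines,
#' computed per trial and averaged when `grouping = "trial"`. Fold
#' accuracies are averaged into one accuracy per run and method.
#'
#' A fold in which any method returns constant predictions (correlation
#' undefined) invalidates that run for all methods, keeping run sets
#' aligned.
#'
#' @param plans a [makeFoldPlan()] result.
#' @param methods named list of functions `f(testLines) -> named gebv`.
#' @param response data.frame with line_id, value and (optionally) trial.
#' @param grouping "none" or "trial".
#' @return a [CVReport-class].
#' @export
runCV <- function(plans, methods, response, grouping = c("none", "trial")) {
  grouping <- match.arg(grouping)
  if (is.null(names(methods))) stop("methods must be a named list")
  if (grouping == "trial" && !"trial" %in% names(response))
    stop("grouping by trial needs a trial column")
  rows <- list()
  badRuns <- integer(0)
  for (plan in plans) {
    run <- plan$run
    for (f in sort(unique(plan$fold))) {
      testLines <- names(plan$fold)[plan$fold == f]
      testResp <- response[response$line_id %in% testLines, , drop = FALSE]
      if (length(unique(testResp$line_id)) < 3)
        stop("test fold with fewer than 3 lines: correlation undefined")
      for (m in names(methods)) {
        g <- methods[[m]](testLines)
        if (grouping == "trial") {
          byTrial <- split(testResp, testResp$trial)
          rs <- vapply(byTrial, function(tr)
            safeCor(g[tr$line_id], tr$value), 0)
          for (trn in names(rs))
            rows[[length(rows) + 1]] <- data.frame(
              run = run, fold = f, method = m, trial = trn, r = rs[[trn]])
          if (anyNA(rs)) badRuns <- union(badRuns, run)
        } else {
          vals <- tapply(testResp$value, testResp$line_id, mean)
          r <- safeCor(g[names(vals)], as.numeric(vals))
          rows[[length(rows) + 1]] <- data.frame(
            run = run, fold = f, method = m, trial = NA_character_, r = r)
          if (is.na(r)) badRuns <- union(badRuns, run)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  if (length(badRuns)) {
    warning("run(s) with undefined correlations excluded for all methods: ",
            paste(badRuns, collapse = ", "))
    results <- results[!results$run %in% badRuns, , drop = FALSE]
  }
  if (nrow(results)) {
    foldMeans <- aggregate(r ~ run + fold + method, data = results,
                           FUN = mean)
    runMeans <- aggregate(r ~ run + method, data = foldMeans, FUN = mean)
    names(runMeans)[names(runMeans) == "r"] <- "accuracy"
  } else {
    runMeans <- data.frame(run = integer(0), method = character(0),
                           accuracy = numeric(0))
  }
  new("CVReport", results = results, runMeans = runMeans,
      methods = names(methods), nRuns = length(unique(results$run)))
}

#' Compare two methods with the win-rate rule
#'
#' Method `a` "wins" a run when its run-mean accuracy strictly exceeds
#' method `b`'s (ties are non-wins). `a` is declared significantly better
#' when its win proportion reaches `threshold` (default 0.9). The mean
#' percent improvement `100 (mean_a - mean_b) / mean_b` is also reported.
#'
#' @param report a [CVReport-class].
#' @param a,b method labels in the report.
#' @param threshold win-proportion cutoff (inclusive).
#' @return list with `wins`, `nRuns`, `winProportion`, `significant`,
#'   `meanA`, `meanB`, `pctImprovement`.
#' @export
compareMethods <- function(report, a, b, threshold = 0.9) {
  rm <- report@runMeans
  if (!all(c(a, b) %in% rm$method)) stop("methods absent from report")
  accA <- rm[rm$method == a, c("run", "accuracy")]
  accB <- rm[rm$method == b, c("run", "accuracy")]
  if (!setequal(accA$run, accB$run)) stop("methods cover different run sets")
  accB <- accB[match(accA$run, accB$run), ]
  wins <- sum(accA$accuracy > accB$accuracy)
  nRuns <- nrow(accA)
  wp <- wins / nRuns
  list(wins = wins, nRuns = nRuns, winProportion = wp,
       significant = wp >= threshold,
       meanA = mean(accA$accuracy), meanB = mean(accB$accuracy),
       pctImprovement = 100 * (mean(accA$accuracy) - mean(accB$accuracy)) /
         abs(mean(accB$accuracy)))
}
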