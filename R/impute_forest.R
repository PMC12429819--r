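#' Iterative random-forest single imputation
#'
#' Re-implementation of the iterative random-forest imputation scheme:
#' gaps are initialized by mean/mode, then variables are revisited in
#' increasing-missingness order, each fitted by a random forest on the
#' rows observing it (predictors are all other model variables, by
#' default including the outcome) and its gaps replaced by forest
#' predictions. Iteration stops the first time the standard difference
#' criterion (normalized squared change for continuous variables,
#' proportion of changed categories for categorical ones) increases for
#' every variable type present, and the previous iteration's fill is
#' returned; otherwise it stops at `max_iter` with a warning.
#'
#' @param table Cohort table with missing cells.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum sweeps over the variables (default 10).
#' @param min_leaf Minimum rows in a leaf (default 5).
#' @param max_depth Depth cap on individual trees (numerical safety;
#'   default 25).
#' @param mtry Candidate predictors per split; default
#'   `floor(sqrt(p))` over the dummy-coded predictor columns.
#' @param use_outcome Include the outcome `bcpr` among the predictors?
#'   Default `TRUE`.
#' @param seed Integer seed; fixes bootstrap and split randomness.
#' @return An [imputed_cohort] with method `"mf"`.
#' @export
impute_missforest <- function(table, n_trees = 100L, max_iter = 10L,
                              min_leaf = 5L, max_depth = 25L, mtry = NULL,
                              use_outcome = TRUE, seed = NULL) {
  stopifnot(n_trees >= 1, max_iter >= 1, min_leaf >= 1)
  table <- as_cohort(table, allow_missing = TRUE)
  mask <- missingness_mask(table)
  gaps <- lapply(amputable_vars, function(v) which(is.na(table[[v]])))
  names(gaps) <- amputable_vars
  n_gap <- vapply(gaps, length, integer(1))
  if (sum(n_gap) == 0L) {
    return(imputed_cohort(table, "mf", mask))
  }
  for (v in amputable_vars) {
    if (n_gap[[v]] > 0L && n_gap[[v]] == nrow(table)) {
      stop("cannot impute fully missing column: ", v)
    }
  }
  vars_order <- names(sort(n_gap[n_gap > 0L]))

  with_seed(seed, {
    work <- impute_mean_mode(table)$table  # initial fill
    prev <- work
    diff_cont_old <- Inf
    diff_cat_old <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      before <- work
      for (v in vars_order) {
        idx <- gaps[[v]]
        obs <- setdiff(seq_len(nrow(work)), idx)
        Xall <- mf_predictors(work, v, use_outcome)
        classif <- v != "age"
        yv <- if (classif) as.numeric(work[[v]][obs]) - 1 else work[[v]][obs]
        m <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(Xall)))) else mtry
        pred <- rf_fit_predict_cpp(
          Xall[obs, , drop = FALSE], yv, Xall[idx, , drop = FALSE],
          as.integer(n_trees), as.integer(m), as.integer(min_leaf),
          as.integer(max_depth), classif,
          if (classif) length(levels(work[[v]])) else 0L
        )
        if (classif) {
          work[[v]][idx] <- levels(work[[v]])[as.integer(pred) + 1L]
        } else {
          work[[v]][idx] <- pred
        }
      }
      # difference criteria between successive fills, imputed cells only
      dc <- mf_diff_cont(work, before, gaps)
      dk <- mf_diff_cat(work, before, gaps)
      # stop on non-decrease for every type present (the reference scheme
      # iterates only while at least one criterion still strictly improves)
      inc_cont <- is.na(dc) || dc >= diff_cont_old
      inc_cat <- is.na(dk) || dk >= diff_cat_old
      if (inc_cont && inc_cat && it > 1L) {
        work <- before  # revert to the previous iteration's fill
        converged <- TRUE
        break
      }
      if (!is.na(dc) && dc == 0 && (is.na(dk) || dk == 0)) {
        converged <- TRUE
        break
      }
      if (is.na(dc) && !is.na(dk) && dk == 0) { converged <- TRUE; break }
      diff_cont_old <- dc
      diff_cat_old <- dk
    }
    if (!converged) {
      warning("random-forest imputation did not converge in ", max_iter,
              " iterations; returning the last fill")
    }
    imputed_cohort(as_cohort(work), "mf", mask)
  })
}

# dummy-coded predictor matrix for imputing variable `target`
mf_predictors <- function(table, target, use_outcome) {
  vars <- setdiff(knn_vars(use_outcome), target)
  cols <- list()
  for (v in vars) {
    x <- table[[v]]
    if (v == "age") {
      cols$age <- as.numeric(x)
    } else if (v %in% c("alert_issued", "bcpr")) {
      cols[[v]] <- as.numeric(x)
    } else if (v == "call_time") {
      cols$call_time <- as.numeric(x)  # ordinal: keep the level code
    } else {
      lv <- levels(x)
      for (l in lv[-1]) cols[[paste0(v, "_", l)]] <- as.numeric(x == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

mf_diff_cont <- function(new, old, gaps) {
  idx <- gaps$age
  if (!length(idx)) return(NA_real_)
  num <- sum((new$age[idx] - old$age[idx])^2)
  den <- sum(new$age[idx]^2)
  if (den == 0) return(0)
  num / den
}

mf_diff_cat <- function(new, old, gaps) {
  n_cells <- 0L; n_changed <- 0L
  for (v in c("witness_type", "call_time")) {
    idx <- gaps[[v]]
    if (!length(idx)) next
    n_cells <- n_cells + length(idx)
    n_changed <- n_changed + sum(new[[v]][idx] != old[[v]][idx])
  }
  if (n_cells == 0L) return(NA_real_)
  n_changed / n_cells
}
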