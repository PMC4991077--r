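# QSPR workflow for the enthalpy of fusion: rank split, GA descriptor
# selection, MLR with leave-one-out and external validation, leverage-based
# applicability domain.

#' Split records into training and validation sets
#'
#' Deterministic rank-based split: records are sorted by the response and
#' every record whose 1-based rank is congruent to 2 modulo 3 goes to
#' validation; the rest (including both extremes) train the model. 30
#' records give 20 training / 10 validation, 6 give 4/2, and the validation
#' range always lies inside the training range.
#'
#' @param records data.frame containing the response
#' @param response name of the response column
#' @return list with \code{training} and \code{validation} data.frames.
#' @export
splitDataset <- function(records, response = "value") {
  if (nrow(records) < 6L) stop("need at least 6 records to split", call. = FALSE)
  if (!response %in% names(records)) {
    stop("no response column \"", response, "\"", call. = FALSE)
  }
  ord <- order(records[[response]])
  rank_ <- integer(nrow(records))
  rank_[ord] <- seq_len(nrow(records))
  val <- rank_ %% 3L == 2L
  list(training = records[!val, , drop = FALSE],
       validation = records[val, , drop = FALSE])
}

.design <- function(X) cbind(`(Intercept)` = 1, as.matrix(X))

#' Fit a multiple linear regression QSPR model
#'
#' Ordinary least squares on the selected descriptors, with training R^2,
#' RMSE and leave-one-out Q^2, and the leverage threshold
#' h* = 3(p+1)/n_train for the applicability domain.
#'
#' @param X training descriptor matrix/data.frame (selected columns only)
#' @param y numeric response (kJ/mol for the enthalpy of fusion)
#' @return a [QSPRModel-class]
#' @export
fitMLR <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes differ", call. = FALSE)
  if (n <= p + 1L) {
    stop(sprintf("need n_train > p + 1 (have n = %d, p = %d)", n, p),
         call. = FALSE)
  }
  M <- .design(X)
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    aliased <- colnames(M)[qr_$pivot[seq.int(qr_$rank + 1L, ncol(M))]]
    stop("singular design: collinear column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  r2 <- min(max(r2, 0), 1)
  stats_ <- list(r2 = r2, rmse_train = sqrt(mean(res^2)),
                 q2_loo = tryCatch(q2Loo(X, y), error = function(e) NA_real_))
  new("QSPRModel",
      descriptors = colnames(X) %||% paste0("x", seq_len(p)),
      coefficients = beta, trainX = X, trainY = y, stats = stats_,
      leverageThreshold = 3 * (p + 1) / n)
}

#' Leave-one-out cross-validated Q^2
#'
#' Q^2 = 1 - PRESS/TSS. The default computes PRESS through the hat-matrix
#' shortcut e_i / (1 - h_i); \code{method = "refit"} performs the n explicit
#' leave-one-out refits. Both agree to 1e-10 on any full-rank design.
#'
#' @param X descriptor matrix
#' @param y response
#' @param method "shortcut" (hat matrix) or "refit" (explicit refits)
#' @return numeric Q^2 (can be negative; never clamped).
#' @export
q2Loo <- function(X, y, method = c("shortcut", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= ncol(X) + 2L) {
    stop("too few rows for leave-one-out validation", call. = FALSE)
  }
  M <- .design(X)
  tss <- sum((y - mean(y))^2)
  if (method == "shortcut") {
    qr_ <- qr(M)
    if (qr_$rank < ncol(M)) stop("singular design", call. = FALSE)
    res <- y - drop(M %*% qr.coef(qr_, y))
    h <- rowSums(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]^2)
    press <- sum((res / (1 - h))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      beta <- qr.coef(qr(M[-i, , drop = FALSE]), y[-i])
      press <- press + (y[i] - drop(M[i, ] %*% beta))^2
    }
  }
  1 - press / tss
}

#' External validation of a fitted QSPR model
#'
#' Q^2_ext = 1 - sum((yhat - y)^2) / sum((y - mean(y_train))^2) and the
#' external RMSE. The validation set must be disjoint from the training set.
#'
#' @param model a [QSPRModel-class]
#' @param Xv validation descriptor matrix (same columns as training)
#' @param yv validation response
#' @return the model with \code{q2_ext}, \code{rmse_ext} added to its stats.
#' @export
externalValidation <- function(model, Xv, yv) {
  stopifnot(is(model, "QSPRModel"))
  Xv <- as.matrix(Xv)[, model@descriptors, drop = FALSE]
  trainKey <- apply(cbind(model@trainX, model@trainY), 1, paste, collapse = "\r")
  valKey <- apply(cbind(Xv, yv), 1, paste, collapse = "\r")
  if (any(valKey %in% trainKey)) {
    stop("validation set overlaps the training set", call. = FALSE)
  }
  pred <- predictQSPR(model, Xv)
  ybar <- mean(model@trainY)
  model@stats$q2_ext <- 1 - sum((pred - yv)^2) / sum((yv - ybar)^2)
  model@stats$rmse_ext <- sqrt(mean((pred - yv)^2))
  model
}

#' Predict with a fitted QSPR model
#'
#' @param model a [QSPRModel-class]
#' @param X descriptor matrix covering the model's descriptors
#' @return numeric predictions.
#' @export
predictQSPR <- function(model, X) {
  X <- as.matrix(X)[, model@descriptors, drop = FALSE]
  drop(.design(X) %*% model@coefficients)
}

.subset_fitness <- function(X, y, idx) {
  tryCatch(q2Loo(X[, idx, drop = FALSE], y), error = function(e) -Inf)
}

#' Genetic-algorithm descriptor selection
#'
#' Searches subsets of a descriptor pool of a fixed model size, maximising
#' the leave-one-out Q^2 of the MLR on the subset. Chromosomes are subsets;
#' tournament selection, uniform subset crossover, point mutation (swap one
#' member for an outside descriptor) and elitism (the best individual always
#' survives, so the final fitness is never below the best random initial
#' one). Fully reproducible for a given seed. Model sizes above n_train/5
#' are capped with a warning (parsimony rule).
#'
#' @param X_pool descriptor pool matrix/data.frame
#' @param y response
#' @param model_size number of descriptors in the model
#' @param population,generations,crossover,mutation GA controls
#' @param seed integer seed driving all GA randomness
#' @return list: \code{selected} (column names), \code{fitness} (its Q^2),
#'   \code{trace} (best fitness per generation).
#' @export
gaSelect <- function(X_pool, y, model_size, population = 50L,
                     generations = 100L, crossover = 0.8, mutation = 0.05,
                     seed = 1L) {
  X_pool <- as.matrix(X_pool)
  pool <- ncol(X_pool)
  nms <- colnames(X_pool) %||% paste0("x", seq_len(pool))
  colnames(X_pool) <- nms
  if (model_size > pool) stop("model_size exceeds the descriptor pool", call. = FALSE)
  cap <- floor(nrow(X_pool) / 5)
  if (model_size > cap) {
    warning(sprintf("model_size %d exceeds n_train/5 = %d; capping (parsimony rule)",
                    model_size, cap))
    model_size <- max(1L, cap)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  popl <- replicate(population, sort(sample.int(pool, model_size)),
                    simplify = FALSE)
  fit <- vapply(popl, function(idx) .subset_fitness(X_pool, y, idx), numeric(1))
  trace <- max(fit)
  for (gen in seq_len(generations)) {
    elite <- popl[[which.max(fit)]]
    nxt <- list(elite)
    while (length(nxt) < population) {
      pick <- function() {
        cand <- sample.int(population, 2L)
        popl[[cand[which.max(fit[cand])]]]
      }
      child <- if (stats::runif(1) < crossover) {
        both <- union(pick(), pick())
        sort(both[sample.int(length(both), model_size)])
      } else pick()
      if (stats::runif(1) < mutation) {
        outside <- setdiff(seq_len(pool), child)
        if (length(outside)) {
          child[sample.int(model_size, 1L)] <- outside[sample.int(length(outside), 1L)]
          child <- sort(child)
        }
      }
      nxt[[length(nxt) + 1L]] <- child
    }
    popl <- nxt
    fit <- vapply(popl, function(idx) .subset_fitness(X_pool, y, idx), numeric(1))
    trace <- c(trace, max(fit))
  }
  best <- popl[[which.max(fit)]]
  list(selected = nms[best], fitness = max(fit), trace = trace)
}

#' Leverage-based applicability domain
#'
#' Leverages h = x' (X'X)^-1 x with intercept-augmented rows; a query lies
#' inside the domain when h <= h* = 3(p+1)/n_train. Training leverages obey
#' 1/n <= h <= 1 and sum to p+1. When observed values are supplied,
#' standardized residuals are reported for a Williams plot.
#'
#' @param model a [QSPRModel-class]
#' @param X_query query descriptor matrix (default: the training set)
#' @param y_query optional observed responses for the queries
#' @return data.frame: leverage, inside flag, and std_residual when
#'   observations were supplied; the \code{"h_star"} attribute carries h*.
#' @export
applicabilityDomain <- function(model, X_query = NULL, y_query = NULL) {
  stopifnot(is(model, "QSPRModel"))
  Xt <- .design(model@trainX)
  XtX <- crossprod(Xt)
  inv <- tryCatch(solve(XtX), error = function(e) {
    stop("singular X'X: applicability domain undefined", call. = FALSE)
  })
  Xq <- if (is.null(X_query)) model@trainX else
    as.matrix(X_query)[, model@descriptors, drop = FALSE]
  Mq <- .design(Xq)
  h <- rowSums((Mq %*% inv) * Mq)
  out <- data.frame(leverage = h, inside = h <= model@leverageThreshold)
  if (!is.null(y_query)) {
    res <- y_query - predictQSPR(model, Xq)
    s <- sqrt(sum((model@trainY - predictQSPR(model, model@trainX))^2) /
                (nrow(model@trainX) - length(model@descriptors) - 1L))
    out$std_residual <- if (s > 0) res / s else res * 0
  }
  attr(out, "h_star") <- model@leverageThreshold
  out
}

#' Run the full QSPR workflow
#'
#' Splits the records, runs the GA on the training pool, fits the MLR on the
#' selected descriptors, and validates externally.
#'
#' @param desc descriptor data.frame with il_id column
#' @param prop property records (il_id, value) for one property
#' @param model_size number of descriptors
#' @param seed GA seed
#' @param ... further GA controls passed to [gaSelect()]
#' @return list: \code{model} ([QSPRModel-class]), \code{ga} (GA result),
#'   \code{williams} (data.frame for the Williams plot), \code{split}.
#' @export
qsprWorkflow <- function(desc, prop, model_size = 3L, seed = 1L, ...) {
  stopifnot("il_id" %in% names(desc), all(c("il_id", "value") %in% names(prop)))
  merged <- merge(prop[, c("il_id", "value")], desc, by = "il_id")
  sp <- splitDataset(merged, "value")
  dcols <- setdiff(names(merged), c("il_id", "value"))
  Xtr <- as.matrix(sp$training[, dcols, drop = FALSE])
  keep <- apply(Xtr, 2, function(v) stats::sd(v) > 1e-12 * max(1, abs(mean(v))))
  Xtr <- Xtr[, keep, drop = FALSE]
  ga <- gaSelect(Xtr, sp$training$value, model_size, seed = seed, ...)
  model <- fitMLR(Xtr[, ga$selected, drop = FALSE], sp$training$value)
  Xv <- as.matrix(sp$validation[, ga$selected, drop = FALSE])
  model <- externalValidation(model, Xv, sp$validation$value)
  ad_tr <- applicabilityDomain(model, y_query = sp$training$value)
  ad_va <- applicabilityDomain(model, Xv, sp$validation$value)
  williams <- rbind(
    data.frame(il_id = sp$training$il_id, set = "training", ad_tr),
    data.frame(il_id = sp$validation$il_id, set = "validation", ad_va))
  list(model = model, ga = ga, williams = williams, split = sp)
}
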