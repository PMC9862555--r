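PREDICTORS <- c("age", "tcpp_r3_per10k", "fvs_r2_per10k",
                "cd206low_linmid_per10k")
MODEL_TERMS <- c("(Intercept)", PREDICTORS, "age:fvs_r2_per10k")

#' Fit the logistic cancer/non-cancer classifier
#'
#' Maximum-likelihood logistic regression of cancer status on age, the TCPP
#' and FVS510 density counts, the CD206-low/lineage-mid count and the
#' age x FVS510-density interaction.  Predictors are deliberately not
#' normalised, keeping the coefficients interpretable on their natural
#' units.  Complete separation is flagged and handled by a ridge-penalised
#' refit.
#'
#' @param features data.frame with columns \code{age},
#'   \code{tcpp_r3_per10k}, \code{fvs_r2_per10k},
#'   \code{cd206low_linmid_per10k}.
#' @param labels binary vector (1/TRUE = cancer).  Samples with missing
#'   labels are excluded from fitting.
#' @param cutoff operating probability cutoff stored with the model.
#' @return a \linkS4class{SputumClassifier}.
#' @export
fitLogistic <- function(features, labels, cutoff = 0.5) {
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  y <- as.integer(as.logical(labels[keep]))
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 samples per class")
  miss <- setdiff(PREDICTORS, colnames(features))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  consts <- vapply(features[PREDICTORS], function(v) sd(v) < 1e-12, TRUE)
  if (any(consts))
    stop("constant predictor(s): ",
         paste(PREDICTORS[consts], collapse = ", "))
  dat <- cbind(features[PREDICTORS], y = y)
  fml <- y ~ age + tcpp_r3_per10k + fvs_r2_per10k + cd206low_linmid_per10k +
    age:fvs_r2_per10k
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || anyNA(coef(fit)) ||
      any(abs(coef(fit)) > 1e4, na.rm = TRUE)) {
    sep <- TRUE
    warning("complete separation detected; using ridge-penalised fallback")
    fit <- ridgeLogistic(fml, dat)
  }
  cf <- coef(fit)[MODEL_TERMS]
  se <- sqrt(diag(vcov(fit)))[MODEL_TERMS]
  pz <- 2 * pnorm(-abs(cf / se))
  new("SputumClassifier", coefficients = cf, se = se, p = pz, cutoff = cutoff,
      separationFlag = sep,
      meta = list(n = length(y), n_cancer = sum(y),
                  n_noncancer = sum(y == 0L)))
}

# lightly ridge-penalised IRLS fallback for separated data; lambda is kept
# tiny so unseparated coefficients are essentially unchanged
ridgeLogistic <- function(fml, dat, lambda = 1e-4) {
  mf <- stats::model.frame(fml, dat)
  X <- stats::model.matrix(fml, mf)
  y <- stats::model.response(mf)
  scale <- apply(X, 2, function(c) max(sd(c), 1e-8))
  scale[1L] <- 1
  P <- diag(lambda / scale^2); P[1L, 1L] <- 0
  beta <- rep(0, ncol(X))
  for (i in 1:100) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  V <- solve(crossprod(X, X * pmax(plogis(drop(X %*% beta)) *
                                     (1 - plogis(drop(X %*% beta))), 1e-10)) + P)
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 vcovm = V, converged = TRUE),
            class = "sputumRidgeFit")
}

#' @export
coef.sputumRidgeFit <- function(object, ...) object$coefficients
#' @export
vcov.sputumRidgeFit <- function(object, ...) object$vcovm

#' Predict the probability of cancer for one feature vector
#'
#' Inverse-logit of b0 + b1 age + b2 tcpp_r3 + b3 fvs_r2 + b4
#' cd206low_linmid + b5 age x fvs_r2.  Refuses samples that failed the
#' eligibility QC.
#'
#' @param m a \linkS4class{SputumClassifier}.
#' @param f named numeric feature vector (as from [extractFeatures()]) or a
#'   one-row data.frame.
#' @param eligible logical; when FALSE the sample is refused with a QC
#'   message rather than scored.
#' @return probability in [0, 1].
#' @export
predictProbability <- function(m, f, eligible = TRUE) {
  if (!isTRUE(eligible))
    stop("QC failure: sample is not eligible for classification ",
         "(insufficient viable singlets or lung macrophages)")
  f <- unlist(f)
  miss <- setdiff(PREDICTORS, names(f))
  if (length(miss)) stop("feature vector lacks: ", paste(miss, collapse = ", "))
  b <- m@coefficients
  eta <- b[["(Intercept)"]] + b[["age"]] * f[["age"]] +
    b[["tcpp_r3_per10k"]] * f[["tcpp_r3_per10k"]] +
    b[["fvs_r2_per10k"]] * f[["fvs_r2_per10k"]] +
    b[["cd206low_linmid_per10k"]] * f[["cd206low_linmid_per10k"]] +
    b[["age:fvs_r2_per10k"]] * f[["age"]] * f[["fvs_r2_per10k"]]
  plogis(eta)
}

#' Turn a probability into a cancer/non-cancer call
#'
#' A sample is called cancer when its probability strictly exceeds the
#' cutoff; at or below the cutoff it is called non-cancer.
#'
#' @param p probability in [0, 1].
#' @param cutoff operating cutoff in [0, 1].
#' @return \code{"cancer"} or \code{"non-cancer"} (vectorised).
#' @export
classifyCall <- function(p, cutoff) {
  stopifnot(all(p >= 0 & p <= 1), cutoff >= 0, cutoff <= 1)
  ifelse(p > cutoff, "cancer", "non-cancer")
}

#' ROC-based cutoff choice
#'
#' Steps through every distinct predicted probability as a candidate
#' cutoff, measuring true and false positive rates against the known
#' labels; returns the full ROC curve, the trapezoid AUC and the cutoff
#' maximising Youden's J (sensitivity + specificity - 1).  Ties on J are
#' broken toward the lower (more sensitive) cutoff.
#'
#' @param probabilities numeric vector of model outputs.
#' @param labels binary vector (1/TRUE = cancer).
#' @return list with \code{cutoff}, \code{roc} (data.frame: cutoff, tpr,
#'   fpr, youden) and \code{auc}.
#' @export
chooseCutoff <- function(probabilities, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  cuts <- sort(unique(probabilities))
  tpr <- vapply(cuts, function(c) sum(probabilities > c & y == 1L) / n1, 0)
  fpr <- vapply(cuts, function(c) sum(probabilities > c & y == 0L) / n0, 0)
  roc <- data.frame(cutoff = c(-Inf, cuts), tpr = c(1, tpr), fpr = c(1, fpr))
  roc$youden <- roc$tpr - roc$fpr
  finite <- roc[is.finite(roc$cutoff), ]
  best <- finite[which.max(finite$youden), ]
  o <- order(roc$fpr, roc$tpr)
  auc <- sum(diff(roc$fpr[o]) * (head(roc$tpr[o], -1) + tail(roc$tpr[o], -1)) / 2)
  list(cutoff = best$cutoff, roc = roc, auc = auc)
}

#' Repeated-split stepwise predictor selection
#'
#' Draws repeated random training subsets that preserve a fixed cancer
#' count (20 of 100 by default, the 20\% cohort ratio) and runs
#' forward/backward stepwise logistic selection on each: a candidate enters
#' when its Wald p-value is below \code{p_enter} and any retained term with
#' Wald p at or above \code{p_remove} is dropped.  Interaction candidates
#' (named \code{"a:b"}) are only eligible while both parents are in the
#' model.  Reports per-variable selection frequencies and the set retained
#' above \code{freq_threshold}.
#'
#' @param candidates data.frame of candidate predictor columns.
#' @param labels binary labels (1 = cancer).
#' @param n_splits number of random training subsets.
#' @param split_size samples per subset (default 100).
#' @param cancer_per_split cancer samples per subset (default 20).
#' @param interactions character vector of \code{"a:b"} interaction
#'   candidates.
#' @param p_enter,p_remove Wald entry/removal thresholds (0.05).
#' @param freq_threshold selection frequency above which a predictor is
#'   retained in the final set.
#' @param seed integer seed.
#' @return list with \code{frequency} (named, sorted) and \code{selected}.
#' @export
stepwiseSelect <- function(candidates, labels, n_splits = 100L,
                           split_size = 100L, cancer_per_split = 20L,
                           interactions = character(),
                           p_enter = 0.05, p_remove = 0.05,
                           freq_threshold = 0.5, seed = 1L) {
  y <- as.integer(as.logical(labels))
  i_can <- which(y == 1L); i_non <- which(y == 0L)
  if (length(i_can) < cancer_per_split ||
      length(i_non) < split_size - cancer_per_split)
    stop("infeasible split sizes for this cohort")
  vars <- colnames(candidates)
  all_terms <- c(vars, interactions)
  hits <- setNames(numeric(length(all_terms)), all_terms)
  for (s in seq_len(n_splits)) {
    idx <- withSeed(childSeed(seed, s), c(
      sample(i_can, cancer_per_split),
      sample(i_non, split_size - cancer_per_split)))
    sel <- stepwiseOneSplit(candidates[idx, , drop = FALSE], y[idx],
                            vars, interactions, p_enter, p_remove)
    hits[sel] <- hits[sel] + 1
  }
  freq <- sort(hits / n_splits, decreasing = TRUE)
  list(frequency = freq, selected = names(freq)[freq > freq_threshold])
}

waldP <- function(fit) {
  cf <- summary(fit)$coefficients
  setNames(cf[, 4L], rownames(cf))
}

stepwiseOneSplit <- function(X, y, vars, interactions, p_enter, p_remove) {
  dat <- cbind(X, .y = y)
  current <- character()
  repeat {
    changed <- FALSE
    # forward: best admissible candidate below p_enter
    parents_ok <- function(term) {
      if (!grepl(":", term)) return(TRUE)
      all(strsplit(term, ":", fixed = TRUE)[[1]] %in% current)
    }
    pool <- setdiff(c(vars, interactions), current)
    pool <- pool[vapply(pool, parents_ok, TRUE)]
    if (length(pool)) {
      pvals <- vapply(pool, function(term) {
        fml <- stats::reformulate(c(current, term), response = ".y")
        fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
        p <- waldP(fit)
        nm <- intersect(names(p), c(term, paste(rev(strsplit(term, ":")[[1]]),
                                                collapse = ":")))
        if (length(nm)) min(p[nm]) else 1
      }, 0)
      if (min(pvals) < p_enter) {
        current <- c(current, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward: drop any retained term at or above p_remove (children first)
    if (length(current)) {
      fml <- stats::reformulate(current, response = ".y")
      fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
      p <- waldP(fit)
      droppable <- current[vapply(current, function(term) {
        !any(grepl(":", current) &
               vapply(current, function(o)
                 grepl(":", o) && term %in% strsplit(o, ":")[[1]], TRUE))
      }, TRUE)]
      p_terms <- vapply(droppable, function(term) {
        nm <- intersect(names(p), c(term, if (grepl(":", term))
          paste(rev(strsplit(term, ":")[[1]]), collapse = ":")))
        if (length(nm)) max(p[nm]) else 0
      }, 0)
      if (length(p_terms) && max(p_terms) >= p_remove) {
        current <- setdiff(current, droppable[which.max(p_terms)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current
}

#' Predictor ablation harness
#'
#' Refits the classifier with each predictor group dropped in turn (age and
#' the FVS510-density variable take their interaction with them) and counts
#' misclassifications at a fixed cutoff, reproducing the
#' impact-of-predictors table layout: a useful predictor's removal should
#' not reduce the error count.
#'
#' @param features cohort feature data.frame (see [fitLogistic()]).
#' @param labels binary labels (1 = cancer).
#' @param cutoff probability cutoff for calls.
#' @return data.frame with rows \code{none} (full model) and one per
#'   dropped predictor: columns \code{cancer_correct},
#'   \code{cancer_incorrect}, \code{noncancer_correct},
#'   \code{noncancer_incorrect}, \code{total_incorrect}.
#' @export
ablationHarness <- function(features, labels, cutoff = 0.5) {
  y <- as.integer(as.logical(labels))
  dat <- cbind(features[PREDICTORS], .y = y)
  groups <- list(
    none = c(PREDICTORS, "age:fvs_r2_per10k"),
    age = c("tcpp_r3_per10k", "fvs_r2_per10k", "cd206low_linmid_per10k"),
    tcpp_r3 = c("age", "fvs_r2_per10k", "cd206low_linmid_per10k",
                "age:fvs_r2_per10k"),
    cd206low_linmid = c("age", "tcpp_r3_per10k", "fvs_r2_per10k",
                        "age:fvs_r2_per10k"),
    fvs_r2 = c("age", "tcpp_r3_per10k", "cd206low_linmid_per10k"),
    `age:fvs_r2` = c(PREDICTORS))
  rows <- lapply(groups, function(tm) {
    fit <- suppressWarnings(glm(stats::reformulate(tm, ".y"), data = dat,
                                family = binomial()))
    call_cancer <- predict(fit, type = "response") > cutoff
    c(cancer_correct = sum(call_cancer & y == 1L),
      cancer_incorrect = sum(!call_cancer & y == 1L),
      noncancer_correct = sum(!call_cancer & y == 0L),
      noncancer_incorrect = sum(call_cancer & y == 0L),
      total_incorrect = sum(call_cancer != (y == 1L)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$dropped <- names(groups)
  out[c("dropped", setdiff(names(out), "dropped"))]
}

#' Save/load a fitted model as JSON
#'
#' @param m a \linkS4class{SputumClassifier}; \code{path} file path.
#' @param path file path.
#' @return \code{readModel()} returns the model.
#' @export
writeModel <- function(m, path) {
  jsonlite::write_json(list(
    coefficients = as.list(m@coefficients),
    se = as.list(m@se), p = as.list(m@p), cutoff = m@cutoff,
    separation = m@separationFlag, meta = m@meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SputumClassifier", coefficients = unlist(j$coefficients),
      se = unlist(j$se), p = unlist(j$p), cutoff = j$cutoff,
      separationFlag = isTRUE(j$separation),
      meta = as.list(j$meta))
}
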