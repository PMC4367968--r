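# Model-(re)building pipeline: correlation pruning, ANOVA screening,
# PCA-based class construction, multinomial fitting, stepwise selection and
# the train/test robustness check.
#
# A training table is an ordinary data frame with one row per image: the 18
# feature columns (Table-style mnemonic names), optionally a `group` label,
# an assigned `class` (0..4) and a `split` flag ("train"/"test").

.FEATURE_ORDER <- c("PCT_LT2", "PCT_LT4", "PCT_LT6", "PCT_LT8",
                    "MPCM", "MPCVAR", "MPCSKEW", "TOTMAX",
                    "DISTM", "DISTVAR", "DISTSKEW",
                    "KURTM", "KURTVAR", "KURTSKEW",
                    "SKEWM", "SKEWVAR", "SKEWSKEW", "LOGNNVAR")

#' Drop highly correlated regularity variables
#'
#' Greedy elimination: constant columns are dropped first (with a warning);
#' then, while any pair of remaining variables exceeds the threshold in
#' absolute Pearson correlation, the member of the worst pair with the
#' larger mean absolute correlation to all remaining variables is removed.
#' Ties are broken by the canonical variable order (the earlier variable is
#' kept). Deterministic.
#'
#' @param table training table (data frame).
#' @param threshold absolute correlation above which a pair is considered
#'   redundant (default 0.9).
#' @param vars candidate variable names; defaults to the 18 feature columns
#'   present in `table`.
#' @return character vector of retained variable names.
#' @export
pruneCorrelated <- function(table, threshold = 0.9, vars = NULL) {
  if (is.null(vars)) vars <- intersect(.FEATURE_ORDER, colnames(table))
  if (nrow(table) < 3L) stop("need at least 3 rows for correlation pruning")
  keep <- vars
  constant <- keep[vapply(keep, function(v) stats::var(table[[v]]) == 0 ||
                                            anyNA(table[[v]]), logical(1))]
  if (length(constant)) {
    warning("dropping constant/NA variables: ",
            paste(constant, collapse = ", "))
    keep <- setdiff(keep, constant)
  }
  # canonical order index for deterministic tie-breaks
  ord <- match(keep, vars)
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(table[keep]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    i <- worst[1]; j <- worst[2]
    mean_abs <- rowMeans(r)
    drop_idx <- if (mean_abs[i] > mean_abs[j]) i
                else if (mean_abs[j] > mean_abs[i]) j
                else if (ord[i] > ord[j]) i else j
    ord <- ord[-drop_idx]
    keep <- keep[-drop_idx]
  }
  keep
}

#' One-way ANOVA screen of the regularity variables
#'
#' For each variable: between- and within-group sums of squares, degrees of
#' freedom (`k - 1` between, `N - k` within), mean squares, the F statistic
#' `s_b^2 / s_w^2` and its p-value from the F distribution. Groups with
#' zero within-variance simply yield an infinite F (p reported as 0).
#'
#' @param table training table.
#' @param groups group labels, one per row (defaults to `table$group`).
#' @param vars variables to screen; defaults to the feature columns.
#' @return data frame with one row per variable: `variable`, `ss_between`,
#'   `ss_within`, `df_between`, `df_within`, `ms_between`, `ms_within`,
#'   `F`, `p`.
#' @export
anovaScreen <- function(table, groups = table$group, vars = NULL) {
  if (is.null(vars)) vars <- intersect(.FEATURE_ORDER, colnames(table))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) stop("every group needs at least 2 rows")
  N <- length(groups); k <- nlevels(groups)
  res <- lapply(vars, function(v) {
    x <- table[[v]]
    grand <- mean(x)
    gm <- tapply(x, groups, mean); gn <- tabulate(groups)
    ssb <- sum(gn * (gm - grand)^2)
    ssw <- sum((x - gm[as.integer(groups)])^2)
    msb <- ssb / (k - 1); msw <- ssw / (N - k)
    f <- if (msb == 0) 0 else msb / msw  # identical rows: F = 0, not 0/0
    data.frame(variable = v, ss_between = ssb, ss_within = ssw,
               df_between = k - 1, df_within = N - k,
               ms_between = msb, ms_within = msw, F = f,
               p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Construct degeneration classes from PC1 scores
#'
#' PCA on the z-scored selected variables (correlation-matrix PCA: the
#' variables live on wildly different scales); the first principal
#' component is then split into `nClasses` ordered clusters by 1-D k-means
#' with deterministic quantile seeding (initial centers at the
#' evenly spaced quantiles of the PC1 scores, then Lloyd iterations).
#' Clusters are ordered along PC1 and relabelled so class 0 is the
#' regular (wild-type-like) end: the end with the lower mean `DISTM`
#' (falling back to `LOGNNVAR`, then to raw PC1 order).
#'
#' @param table training table.
#' @param nClasses number of ordered classes (default 5).
#' @param vars variables entering the PCA; defaults to the feature columns.
#' @return list with `class` (integer labels, 0-based), `pc1` (scores),
#'   `explained` (per-component variance fractions), `centers` (ordered
#'   cluster centers on PC1).
#' @export
pcaCluster <- function(table, nClasses = 5, vars = NULL) {
  if (is.null(vars)) vars <- intersect(.FEATURE_ORDER, colnames(table))
  X <- scale(as.matrix(table[vars]))
  if (nrow(X) < nClasses) stop("need at least nClasses rows")
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  if (length(unique(pc1)) < nClasses)
    stop("fewer distinct PC1 scores (", length(unique(pc1)),
         ") than classes (", nClasses, ")")
  explained <- pca$sdev^2 / sum(pca$sdev^2)

  if (nClasses == 1L) {
    labels <- rep(0L, length(pc1)); centers <- mean(pc1)
  } else {
    centers <- unname(stats::quantile(pc1, probs = seq(0.5, nClasses - 0.5,
                                                       by = 1) / nClasses))
    for (it in 1:100) {
      assign <- apply(outer(pc1, centers, function(a, b) abs(a - b)), 1,
                      which.min)
      new_centers <- vapply(seq_len(nClasses), function(k)
        if (any(assign == k)) mean(pc1[assign == k]) else centers[k],
        numeric(1))
      if (max(abs(new_centers - centers)) < 1e-12) break
      centers <- new_centers
    }
    o <- order(centers)
    labels <- match(assign, o) - 1L
    centers <- centers[o]
  }
  # orientation: class 0 must be the regular end
  anchor <- intersect(c("DISTM", "LOGNNVAR"), vars)
  if (length(anchor)) {
    a <- table[[anchor[1]]]
    if (stats::cor(a, pc1) < 0) {  # low PC1 = degenerate: flip
      labels <- (nClasses - 1L) - labels
      centers <- rev(centers)
    }
  }
  list(class = labels, pc1 = unname(pc1), explained = unname(explained),
       centers = centers)
}

# Newton-Raphson maximum likelihood for the multinomial logit with the
# last class as reference. X: n x p design (with intercept), y: 1..K.
.fit_multinom_core <- function(X, y, K, maxit = 200, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  beta <- matrix(0, K - 1, p)
  Y <- sapply(seq_len(K - 1), function(k) as.numeric(y == k))
  if (is.vector(Y)) Y <- matrix(Y, ncol = K - 1)
  probs <- function(beta) {
    A <- cbind(X %*% t(beta), 0)
    A <- A - apply(A, 1, max)
    E <- exp(A)
    E / rowSums(E)
  }
  loglik <- function(beta) {
    P <- probs(beta)
    sum(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- probs(beta)
    G <- t(Y - P[, seq_len(K - 1), drop = FALSE]) %*% X  # (K-1) x p
    H <- matrix(0, (K - 1) * p, (K - 1) * p)
    for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
      W <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
        t(X) %*% (X * W)
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), as.vector(t(G))),
                     error = function(e) solve(H + diag(1e-4, nrow(H)),
                                               as.vector(t(G))))
    step_m <- matrix(step, K - 1, p, byrow = TRUE)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step_m
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step_m
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { converged <- TRUE
      ll <- ll_new; break }
    ll <- ll_new
  }
  P <- probs(beta)
  H <- matrix(0, (K - 1) * p, (K - 1) * p)
  for (k in seq_len(K - 1)) for (l in seq_len(K - 1)) {
    W <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
    H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
      t(X) %*% (X * W)
  }
  se <- tryCatch(matrix(sqrt(diag(solve(H))), K - 1, p, byrow = TRUE),
                 error = function(e) matrix(NA_real_, K - 1, p))
  # complete separation: the fit drives every observation's own-class
  # probability to 1 (zero deviance), or the Newton iteration diverged
  perfect <- all(P[cbind(seq_len(n), y)] > 1 - 1e-6)
  separated <- !converged || max(abs(beta)) > 1e3 || anyNA(se) || perfect
  list(beta = beta, se = se, loglik = ll, converged = converged,
       separated = separated, fitted = P)
}

#' Fit the multinomial logistic degeneration model
#'
#' Maximum-likelihood multinomial logit of the assigned class (0..4, class
#' 4 = reference, matching the built-in coefficient layout) on the selected
#' variables, by Newton-Raphson with analytic Hessian and step-halving.
#' If the table carries a `split` column, only `"train"` rows are fitted
#' and held-out accuracy is evaluated on the `"test"` rows. Quasi- or
#' complete separation is detected (diverging coefficients or standard
#' errors) and flagged with a warning rather than silently returned.
#'
#' @param table training table with a `class` column.
#' @param selectedVars predictor column names (default: the three model
#'   features `DISTM`, `DISTSKEW`, `LOGNNVAR`).
#' @return list with `coefficients` ((K-1) x (1+p) matrix in built-in
#'   layout), `se` (matching standard errors), `loglik`, `converged`,
#'   `separated`, `testAccuracy` (`NA` without a test split), and `model`
#'   (an [EyeModel], when fitted on exactly the three model features with
#'   five classes).
#' @export
fitMultinomial <- function(table,
                           selectedVars = c("DISTM", "DISTSKEW", "LOGNNVAR")) {
  if (!length(selectedVars)) stop("selectedVars must be non-empty")
  stopifnot("class" %in% colnames(table))
  train <- if ("split" %in% colnames(table)) table[table$split == "train", ]
           else table
  classes <- sort(unique(table$class))
  K <- length(classes)
  if (length(setdiff(unique(train$class), classes)))
    stop("train split holds classes absent from the table")
  if (K < 2L) stop("need at least 2 classes")
  y <- match(train$class, classes)
  X <- cbind(1, as.matrix(train[selectedVars]))
  fit <- .fit_multinom_core(X, y, K)
  if (fit$separated)
    warning("possible complete separation: coefficients/standard errors ",
            "diverged; estimates are unreliable")
  dn <- list(paste0("class", classes[-K]), c("independent", selectedVars))
  dimnames(fit$beta) <- dn
  dimnames(fit$se) <- dn

  test_acc <- NA_real_
  if ("split" %in% colnames(table) && any(table$split == "test")) {
    test <- table[table$split == "test", ]
    Xt <- cbind(1, as.matrix(test[selectedVars]))
    A <- cbind(Xt %*% t(fit$beta), 0)
    pred <- classes[apply(A, 1, which.max)]
    test_acc <- mean(pred == test$class)
  }
  model <- NULL
  if (K == 5L && identical(selectedVars, c("DISTM", "DISTSKEW", "LOGNNVAR")))
    model <- eyeModel(fit$beta, description = "refit on training table")
  list(coefficients = fit$beta, se = fit$se, loglik = fit$loglik,
       converged = fit$converged, separated = fit$separated,
       testAccuracy = test_acc, model = model)
}

#' Forward-stepwise variable selection on the multinomial likelihood
#'
#' Forward selection with likelihood-ratio entry tests (default entry
#' significance 0.05) followed after each addition by a backward check
#' removing variables whose exit test exceeds the stay threshold (default
#' 0.10). Deterministic: candidates are scanned in the given order and the
#' smallest entry p-value wins.
#'
#' @param table training table with a `class` column.
#' @param candidateVars candidate predictor names.
#' @param enter,stay entry/stay significance thresholds.
#' @return character vector of selected variables, in entry order (empty,
#'   with a warning, if nothing passes).
#' @export
stepwiseSelect <- function(table, candidateVars, enter = 0.05, stay = 0.10) {
  if (length(candidateVars) < 1L) stop("need candidate variables")
  train <- if ("split" %in% colnames(table)) table[table$split == "train", ]
           else table
  classes <- sort(unique(train$class))
  K <- length(classes)
  y <- match(train$class, classes)
  dev <- function(vars) {
    X <- if (length(vars)) cbind(1, as.matrix(train[vars]))
         else matrix(1, nrow(train), 1)
    -2 * .fit_multinom_core(X, y, K)$loglik
  }
  selected <- character(0)
  d_cur <- dev(selected)
  repeat {
    pool <- setdiff(candidateVars, selected)
    if (!length(pool)) break
    trial <- vapply(pool, function(v) dev(c(selected, v)), numeric(1))
    pvals <- stats::pchisq(d_cur - trial, df = K - 1, lower.tail = FALSE)
    best <- which.min(pvals)
    if (pvals[best] >= enter) break
    selected <- c(selected, pool[best])
    d_cur <- trial[best]
    # backward pass at the stay threshold
    repeat {
      if (length(selected) < 2L) break
      drop_p <- vapply(selected, function(v) {
        stats::pchisq(dev(setdiff(selected, v)) - d_cur, df = K - 1,
                      lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] <= stay) break
      selected <- selected[-worst]
      d_cur <- dev(selected)
    }
  }
  if (!length(selected)) warning("no variable passed the entry threshold")
  selected
}

#' Robustness of IREG to the train/test division
#'
#' Refits the model on several random train/test divisions of the table and
#' scores every image under each refit, echoing the check that the
#' regularity index should not depend on which images trained the model.
#'
#' @param table training table with `class`, feature columns and optionally
#'   `group` (defaults to the class labels).
#' @param nSplits number of random divisions (default 3).
#' @param seed RNG seed for the divisions.
#' @param trainFrac fraction of rows in each training split.
#' @param selectedVars predictors (default: the three model features).
#' @return list with `perSplit` (matrix: groups x splits of group-mean
#'   IREG), `maxAcrossSplitDiff` (largest across-split range of a group
#'   mean), `betweenGroupDiff` (range of the split-averaged group means;
#'   `NA` dispersion summary when `nSplits == 1`).
#' @export
robustnessCheck <- function(table, nSplits = 3, seed = 1, trainFrac = 0.7,
                            selectedVars = c("DISTM", "DISTSKEW",
                                             "LOGNNVAR")) {
  groups <- if ("group" %in% colnames(table)) factor(table$group)
            else factor(table$class)
  set.seed(seed)
  n <- nrow(table)
  per_split <- matrix(NA_real_, nlevels(groups), nSplits,
                      dimnames = list(levels(groups),
                                      paste0("split", seq_len(nSplits))))
  for (s in seq_len(nSplits)) {
    idx <- sample.int(n, round(trainFrac * n))
    tab <- table
    tab$split <- "test"; tab$split[idx] <- "train"
    # every class must appear in the training rows; resample if not
    tries <- 0
    while (length(unique(tab$class[tab$split == "train"])) <
           length(unique(tab$class)) && tries < 50) {
      idx <- sample.int(n, round(trainFrac * n))
      tab$split <- "test"; tab$split[idx] <- "train"
      tries <- tries + 1
    }
    fit <- fitMultinomial(tab, selectedVars)
    B <- fit$coefficients
    A <- cbind(cbind(1, as.matrix(table[selectedVars])) %*% t(B), 0)
    A <- A - apply(A, 1, max)
    P <- exp(A) / rowSums(exp(A))
    ireg <- as.numeric(P %*% c(4, 3, 2, 1, 0)) / 4
    per_split[, s] <- tapply(ireg, groups, mean)
  }
  group_means <- rowMeans(per_split)
  list(perSplit = per_split,
       maxAcrossSplitDiff = if (nSplits > 1)
         max(apply(per_split, 1, function(x) diff(range(x)))) else NA_real_,
       betweenGroupDiff = diff(range(group_means)))
}
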