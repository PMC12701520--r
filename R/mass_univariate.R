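#' TFCE and permutation parameters
#'
#' Defaults follow standard practice for threshold-free cluster enhancement
#' on statistical maps: extent exponent `E = 0.5`, height exponent `H = 2`,
#' threshold step `dh = 0.01`, 10,000 permutations.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh threshold integration step, in units of the statistic (> 0).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param alpha family-wise error rate level.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = 0.01, n_perm = 10000,
                        seed = 1, alpha = 0.05) {
  stopifnot(E >= 0, H >= 0, dh > 0, n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(E = E, H = H, dh = dh, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alpha = alpha),
            class = "tfce_params")
}

as_design_matrix <- function(design) {
  if (is.data.frame(design)) {
    model.matrix(~ ., data = design)
  } else {
    as.matrix(design)
  }
}

#' Two-group design matrix and contrast
#'
#' Builds an intercept + group-indicator (+ optional numeric covariates)
#' design with a contrast selecting the group effect (second level minus
#' first).
#'
#' @param groups factor/character of two group labels.
#' @param covariates optional data frame of numeric covariates.
#' @return list with `X` (design matrix) and `contrast` (vector).
#' @export
two_group_design <- function(groups, covariates = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_lateq("exactly two group levels required")
  df <- data.frame(group = groups)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- model.matrix(~ ., data = df)
  contrast <- as.numeric(colnames(X) == paste0("group", levels(groups)[2]))
  list(X = X, contrast = contrast)
}

#' Per-vertex GLM contrast t statistics
#'
#' Ordinary least squares at every vertex with a shared design matrix;
#' returns the t statistic for a linear contrast of the coefficients
#' (two-sided convention: the sign carries direction, inference uses `|t|`).
#' Vertices with any non-finite data are flagged `NA`.
#'
#' @param data subjects x vertices numeric matrix.
#' @param design design matrix (or data frame expanded via
#'   [stats::model.matrix()]); rows align with `data`.
#' @param contrast numeric contrast vector over design columns.
#' @return per-vertex t statistics.
#' @export
glm_tstat_map <- function(data, design, contrast) {
  X <- as_design_matrix(design)
  data <- as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(data) != n) stop_lateq("data rows (%d) != design rows (%d)",
                                  nrow(data), n)
  if (length(contrast) != p) stop_lateq("contrast length != design columns")
  if (qr(X)$rank < p) stop_lateq("rank-deficient design matrix")
  if (n <= p) stop_lateq("no residual degrees of freedom (n = %d, p = %d)", n, p)
  ok <- colSums(!is.finite(data)) == 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  tval <- rep(NA_real_, ncol(data))
  if (any(ok)) {
    y <- data[, ok, drop = FALSE]
    beta <- XtXinv %*% crossprod(X, y)
    res <- y - X %*% beta
    sigma2 <- colSums(res^2) / (n - p)
    cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
    tval[ok] <- drop(crossprod(contrast, beta)) / sqrt(cvar * sigma2)
  }
  tval
}

#' Threshold-free cluster enhancement on a mesh
#'
#' `TFCE(v) = sum over h = dh, 2dh, ... of e_v(h)^E * h^H * dh`, where
#' `e_v(h)` is the vertex count of the connected suprathreshold component
#' containing `v` at height `h`. Negative map values are enhanced on the
#' negated map and returned with their sign, so positive and negative effects
#' are treated symmetrically.
#'
#' @param stat_map per-vertex statistic values (finite; `NA` allowed and
#'   propagated).
#' @param mesh a [make_mesh()] graph.
#' @param params a [tfce_params()] object.
#' @return per-vertex signed TFCE scores.
#' @export
tfce_transform <- function(stat_map, mesh, params) {
  validate_mesh(mesh)
  stopifnot(inherits(params, "tfce_params"))
  if (length(stat_map) != mesh$n_vertices) {
    stop_lateq("stat map length != vertex count")
  }
  na <- is.na(stat_map)
  x <- ifelse(na, 0, stat_map)
  pos <- tfce_nonneg_cpp(pmax(x, 0), mesh$edges, params$E, params$H, params$dh)
  neg <- tfce_nonneg_cpp(pmax(-x, 0), mesh$edges, params$E, params$H, params$dh)
  out <- pos - neg
  out[na] <- NA_real_
  out
}

#' Max-statistic TFCE permutation FWER inference
#'
#' Family-wise-error-corrected p values from the permutation distribution of
#' the maximum absolute TFCE score across vertices. Nuisance covariates
#' (design columns with zero contrast weight) are handled by Freedman-Lane
#' residual permutation: reduced-model residuals are permuted and the
#' reduced-model fit added back before recomputing the full-model contrast.
#' For a pure two-group design (single binary effect column, intercept-only
#' nuisance) whose number of distinct label assignments does not exceed
#' `n_perm`, the exact enumeration over all assignments is used instead of
#' Monte Carlo sampling.
#'
#' @inheritParams glm_tstat_map
#' @param mesh a [make_mesh()] graph.
#' @param params a [tfce_params()] object (`n_perm`, `seed`, TFCE exponents).
#' @return list: `p` (per-vertex FWER-corrected p), `t`, `tfce` (observed
#'   maps), `max_null` (null max-TFCE distribution), `method`
#'   (`"enumeration"` or `"montecarlo"`).
#' @export
permutation_fwer <- function(data, design, contrast, mesh, params) {
  X <- as_design_matrix(design)
  data <- as.matrix(data)
  stopifnot(inherits(params, "tfce_params"))
  effect_cols <- which(contrast != 0)
  nuis_cols <- setdiff(seq_len(ncol(X)), effect_cols)
  n <- nrow(X)
  t_obs <- glm_tstat_map(data, X, contrast)
  tfce_obs <- tfce_transform(t_obs, mesh, params)

  eff <- X[, effect_cols, drop = FALSE]
  enum_ok <- length(effect_cols) == 1 && all(eff %in% c(0, 1)) &&
    length(nuis_cols) == 1 && all(X[, nuis_cols] == 1)
  n1 <- if (enum_ok) sum(eff) else NA
  if (enum_ok && params$n_perm >= choose(n, n1)) {
    combs <- utils::combn(n, n1)
    max_null <- numeric(ncol(combs))
    for (b in seq_len(ncol(combs))) {
      Xb <- X
      Xb[, effect_cols] <- 0
      Xb[combs[, b], effect_cols] <- 1
      tb <- glm_tstat_map(data, Xb, contrast)
      max_null[b] <- max(abs(tfce_transform(tb, mesh, params)), na.rm = TRUE)
    }
    p <- vapply(abs(tfce_obs),
                function(v) mean(max_null >= v - 1e-12), numeric(1))
    method <- "enumeration"
  } else {
    Z <- X[, nuis_cols, drop = FALSE]
    fitted_red <- Z %*% solve(crossprod(Z), crossprod(Z, data))
    R <- data - fitted_red
    set_seed_strict(params$seed)
    max_null <- numeric(params$n_perm)
    for (b in seq_len(params$n_perm)) {
      perm <- sample.int(n)
      tb <- glm_tstat_map(fitted_red + R[perm, , drop = FALSE], X, contrast)
      max_null[b] <- max(abs(tfce_transform(tb, mesh, params)), na.rm = TRUE)
    }
    p <- vapply(abs(tfce_obs), function(v) {
      (1 + sum(max_null >= v - 1e-12)) / (params$n_perm + 1)
    }, numeric(1))
    method <- "montecarlo"
  }
  p[is.na(tfce_obs)] <- NA_real_
  list(p = p, t = t_obs, tfce = tfce_obs, max_null = max_null,
       method = method)
}

#' Per-vertex longitudinal mixed-effects interaction map
#'
#' Fits, at every vertex, `thickness ~ time + group + covariates +
#' time:group + (1 | subject)` and returns the time x group interaction
#' (atrophy-rate difference of the second group level vs the first) with its
#' Wald SE and normal-approximation p value. Vertices whose fit fails to
#' converge are flagged with missing results.
#'
#' @param data visits x vertices numeric matrix.
#' @param meta data frame aligned with `data` rows: `subject_id`, `time`
#'   (years), `group` (exactly two levels), plus any covariate columns.
#' @param covariates character vector of covariate column names in `meta`
#'   (default `"age"`).
#' @return data frame: `vertex`, `estimate` (units/year), `se`, `p`,
#'   `converged`.
#' @export
lme_interaction_map <- function(data, meta, covariates = "age") {
  data <- as.matrix(data)
  stopifnot(nrow(data) == nrow(meta))
  meta$group <- factor(meta$group)
  if (nlevels(meta$group) != 2) stop_lateq("exactly two group levels required")
  nvis <- table(meta$subject_id)
  if (max(nvis) < 2 || var(meta$time) == 0) {
    stop_lateq("longitudinal model requires repeated visits with varying time (cross-sectional data supplied)")
  }
  rhs <- paste(c("time", "group", covariates, "time:group",
                 "(1 | subject_id)"), collapse = " + ")
  form <- as.formula(paste("y ~", rhs))
  term <- paste0("time:group", levels(meta$group)[2])
  out <- data.frame(vertex = seq_len(ncol(data)), estimate = NA_real_,
                    se = NA_real_, p = NA_real_, converged = FALSE)
  for (v in seq_len(ncol(data))) {
    df <- meta
    df$y <- data[, v]
    if (any(!is.finite(df$y))) next
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = df,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- lme4::fixef(fit)
    if (!term %in% names(cf)) next
    se <- sqrt(diag(as.matrix(vcov(fit))))[term]
    out$estimate[v] <- unname(cf[term])
    out$se[v] <- unname(se)
    out$p[v] <- 2 * pnorm(-abs(cf[term] / se))
    out$converged[v] <- TRUE
  }
  out
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment: `q_i = min over j >= i of m * p_(j) / j` (capped
#' at 1), returned in the input order.
#'
#' @param p_values vector of p values in `[0, 1]` (`NA` allowed, propagated).
#' @return BH-adjusted q values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_lateq("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
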