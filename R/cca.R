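#' Preprocess parameter and symptom tables for canonical correlation
#'
#' Replaces the two initial-expectation parameters with their average and
#' range (two summary variables carrying the same information), screens each
#' parameter column for normality (Shapiro-Wilk at `alpha`) and
#' log-transforms failing columns (adding an offset of `1e-6 - min` when a
#' column is not strictly positive), then z-scores every column of both
#' blocks.
#'
#' @param params Data frame of per-subject parameters; if columns
#'   `esv1_init`/`esv4_init` are present they are replaced by `avg_init` and
#'   `range_init` (existing `avg_init`/`range_init` columns are used as-is).
#'   A `subject` column is ignored.
#' @param symptoms Data frame of per-subject symptom scores (z-scored here
#'   regardless of input scale).
#' @param alpha Normality-screen level for the log-transform decision; set
#'   to 0 to disable transformation.
#' @return A list of class `"esteem_cca_input"` with matrices `X`
#'   (subjects x parameters) and `Y` (subjects x scales), both z-scored,
#'   and `log_transformed`, the names of transformed parameter columns.
#' @export
cca_preprocess <- function(params, symptoms, alpha = 0.05) {
  X <- as.data.frame(params)
  X$subject <- NULL
  if (all(c("esv1_init", "esv4_init") %in% names(X))) {
    avg <- (X$esv1_init + X$esv4_init) / 2
    rng <- X$esv1_init - X$esv4_init
    X$esv1_init <- NULL
    X$esv4_init <- NULL
    X$avg_init <- avg
    X$range_init <- rng
  }
  Y <- as.data.frame(symptoms)
  Y$subject <- NULL
  if (nrow(X) != nrow(Y)) stop("params and symptoms differ in subject count")
  if (nrow(X) < max(ncol(X), ncol(Y)) + 2)
    stop("need at least max(block size) + 2 subjects")

  logged <- character(0)
  if (alpha > 0) {
    for (nm in names(X)) {
      v <- X[[nm]]
      if (stats::sd(v) == 0) next
      p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 1)
      if (p < alpha) {
        offset <- if (min(v) <= 0) 1e-6 - min(v) else 0
        if (min(v + offset) <= 0)
          stop("cannot log-transform column ", nm)
        X[[nm]] <- log(v + offset)
        logged <- c(logged, nm)
      }
    }
  }
  zX <- zscore_columns(as.matrix(X))
  zY <- zscore_columns(as.matrix(Y))
  structure(list(X = zX, Y = zY, log_transformed = logged),
            class = "esteem_cca_input")
}

zscore_columns <- function(M) {
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "),
         "; remove before z-scoring")
  scale(M)
}

#' Canonical correlation between model parameters and symptom scales
#'
#' Solves the standard canonical-correlation problem on the two z-scored
#' blocks (via [stats::cancor()]), computes Wilks' lambda with Rao's F
#' approximation for every dimension, standardises the weights so each
#' canonical variate has unit sample variance, and fixes the sign of each
#' dimension so that the `trait_self_esteem` coefficient (or the first
#' symptom column if that name is absent) is negative — higher scores then
#' mean greater vulnerability.
#'
#' @param input An `"esteem_cca_input"` from [cca_preprocess()], or a list
#'   with z-scored matrices `X` and `Y`.
#' @param orient_column Symptom column whose coefficient is forced negative
#'   on every dimension.
#' @return An object of class `"esteem_cca"`: `cor` (canonical correlations,
#'   descending), `x_coef`, `y_coef` (standardised weights, one column per
#'   dimension), `wilks` (data frame with `lambda`, `f`, `df1`, `df2`,
#'   `p_value` per dimension), `x_scores`, `y_scores` (unit-variance subject
#'   scores), and `n`.
#' @export
esteem_cca <- function(input, orient_column = "trait_self_esteem") {
  X <- input$X
  Y <- input$Y
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  if (n <= max(p, q)) stop("need more subjects than variables per block")
  if (qr(X)$rank < p || qr(Y)$rank < q)
    stop("rank-deficient block; remove collinear columns")
  if (n < 5 * max(p, q))
    warning("only ", n, " subjects for blocks of size ", p, " and ", q,
            "; canonical correlations will be strongly inflated")
  cc <- stats::cancor(X, Y, xcenter = TRUE, ycenter = TRUE)
  s <- min(p, q)
  rho <- cc$cor[seq_len(s)]

  xc <- cc$xcoef[, seq_len(s), drop = FALSE]
  yc <- cc$ycoef[, seq_len(s), drop = FALSE]
  xs <- scale(X, center = TRUE, scale = FALSE) %*% xc
  ys <- scale(Y, center = TRUE, scale = FALSE) %*% yc
  # rescale weights so every variate has unit sample variance
  xsd <- apply(xs, 2, stats::sd)
  ysd <- apply(ys, 2, stats::sd)
  xc <- sweep(xc, 2, xsd, "/")
  yc <- sweep(yc, 2, ysd, "/")
  xs <- sweep(xs, 2, xsd, "/")
  ys <- sweep(ys, 2, ysd, "/")

  orient <- if (orient_column %in% rownames(yc)) orient_column
            else rownames(yc)[1]
  flip <- sign(yc[orient, ])
  flip[flip == 0] <- 1
  xc <- sweep(xc, 2, -flip, "*")
  yc <- sweep(yc, 2, -flip, "*")
  xs <- sweep(xs, 2, -flip, "*")
  ys <- sweep(ys, 2, -flip, "*")

  wilks <- rao_wilks(rho, n, p, q)
  structure(list(cor = rho, x_coef = xc, y_coef = yc, wilks = wilks,
                 x_scores = xs, y_scores = ys, n = n, p = p, q = q),
            class = "esteem_cca")
}

# Wilks' lambda and Rao's F approximation for dimensions d..s, one row per
# starting dimension.
rao_wilks <- function(rho, n, p, q) {
  s <- length(rho)
  out <- data.frame(dimension = seq_len(s), lambda = NA_real_, f = NA_real_,
                    df1 = NA_real_, df2 = NA_real_, p_value = NA_real_)
  for (d in seq_len(s)) {
    p1 <- p - d + 1
    q1 <- q - d + 1
    lam <- prod(1 - rho[d:s] ^ 2)
    tt <- if (p1 ^ 2 + q1 ^ 2 - 5 > 0)
      sqrt((p1 ^ 2 * q1 ^ 2 - 4) / (p1 ^ 2 + q1 ^ 2 - 5)) else 1
    df1 <- p1 * q1
    df2 <- (n - 1.5 - (p1 + q1) / 2) * tt - df1 / 2 + 1
    lam_t <- lam ^ (1 / tt)
    fstat <- ((1 - lam_t) / lam_t) * df2 / df1
    out$lambda[d] <- lam
    out$f[d] <- fstat
    out$df1[d] <- df1
    out$df2[d] <- df2
    out$p_value[d] <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  out
}

#' Subject scores on a canonical dimension
#'
#' Returns the symptom-block canonical variate (the vulnerability score when
#' `dimension = 1`): a unit-variance weighted combination of symptom scales,
#' oriented so that higher values mean greater vulnerability.
#'
#' @param result An `"esteem_cca"`.
#' @param dimension Dimension index.
#' @return Numeric vector of per-subject scores.
#' @export
subject_scores <- function(result, dimension = 1) {
  stopifnot(inherits(result, "esteem_cca"),
            dimension >= 1, dimension <= length(result$cor))
  as.numeric(result$y_scores[, dimension])
}

#' @export
print.esteem_cca <- function(x, digits = 3, ...) {
  cat("Canonical correlation analysis: ", x$p, " parameters x ", x$q,
      " symptom scales, n = ", x$n, "\n", sep = "")
  w <- x$wilks[1, ]
  cat(sprintf("  first dimension: r = %.3f, Wilks lambda = %.3g, F(%g, %.1f) = %.2f, p = %.3g\n",
              x$cor[1], w$lambda, w$df1, w$df2, w$f, w$p_value))
  cat("  canonical correlations:", paste(round(x$cor, digits),
                                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.esteem_cca <- function(x, dimension = 1, ...) {
  coefs <- c(x$x_coef[, dimension], x$y_coef[, dimension])
  block <- rep(c("parameter", "symptom"),
               c(nrow(x$x_coef), nrow(x$y_coef)))
  op <- graphics::par(mar = c(5, 11, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(coefs), horiz = TRUE, las = 1,
                    names.arg = rev(names(coefs)),
                    col = rev(ifelse(block == "parameter",
                                     "steelblue", "firebrick")),
                    xlab = "standardised canonical coefficient",
                    main = paste("Canonical dimension", dimension), ...)
  invisible(x)
}
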