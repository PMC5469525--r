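#' Reference matrix of a feature table
#'
#' Column means of the healthy training feature matrix; each feature's
#' mean over all training AGGs serves as its nominal healthy value.
#'
#' @param X numeric matrix, rows = AGG-level feature vectors, columns =
#'   features in the fixed order (P, V, N, H, S).
#' @return named numeric vector of column means.
#' @export
build_reference_matrix <- function(X) {
  X <- rbind(X)
  xref <- colMeans(X)
  if (any(xref == 0))
    stop("degenerate reference column: zero mean feature")
  xref
}

#' Normalize feature rows to positive indicators
#'
#' Comprehensive grey relational generating transform: values at the
#' healthy reference map to 1, and deviation to either side lowers the
#' indicator symmetrically,
#' \deqn{Z_{ij} = x_{ij}/X_{ref,j}} for \eqn{x \le X_{ref}} and
#' \deqn{Z_{ij} = 2 - x_{ij}/X_{ref,j}} otherwise. Values beyond twice
#' the reference go negative and are deliberately not clamped; they
#' simply produce large deviations and low similarity downstream.
#'
#' @param X feature matrix (rows = AGGs).
#' @param xref reference vector from [build_reference_matrix()].
#' @return normalized matrix Z of the same shape.
#' @export
normalize_features <- function(X, xref) {
  X <- rbind(X)
  if (!all(is.finite(X))) stop("non-finite feature values")
  Z <- sweep(X, 2L, xref, "/")
  high <- sweep(X, 2L, xref, ">")
  Z[high] <- 2 - Z[high]
  Z
}

#' Reference set of a normalized feature matrix
#'
#' @param Z normalized matrix from [normalize_features()].
#' @return named numeric vector of column means (the reference set R).
#' @export
build_reference_set <- function(Z) {
  colMeans(rbind(Z))
}

#' Global extrema of training deviations
#'
#' Minimum and maximum of `|Z(i,j) - R(j)|` over all training rows and
#' features; these scale the grey relational coefficient.
#'
#' @param Z normalized training matrix.
#' @param R reference set.
#' @return numeric `c(minAbs, maxAbs)`.
#' @export
compute_extrema <- function(Z, R) {
  dev <- abs(sweep(rbind(Z), 2L, R))
  c(minAbs = min(dev), maxAbs = max(dev))
}

#' Fit the grey relational gait assessment model
#'
#' Fits the reference model from the feature vectors of healthy
#' training subjects (four AGG-level rows per subject): the reference
#' matrix Xref (column means), the normalized reference set R, the
#' global deviation extrema minAbs / maxAbs, the distinguishing
#' coefficient gamma and the feature weights. New subjects are scored
#' with [predict.gait_grm()].
#'
#' @param healthy_features numeric matrix (or data.frame) of AGG-level
#'   feature vectors of healthy subjects, columns (P, V, N, H, S).
#' @param gamma distinguishing coefficient in (0, 1] (default 1).
#' @param weights feature weights summing to 1 (default equal, 0.2
#'   each).
#' @param subject_ids optional row grouping labels, stored for
#'   provenance.
#' @return an object of class `gait_grm`.
#' @export
fit_gait_model <- function(healthy_features, gamma = 1,
                           weights = rep(1 / 5, 5), subject_ids = NULL) {
  X <- as.matrix(healthy_features)
  if (is.null(colnames(X))) colnames(X) <- FEATURE_ORDER
  X <- X[, FEATURE_ORDER, drop = FALSE]
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (length(weights) != ncol(X) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must have one entry per feature and sum to 1")
  xref <- build_reference_matrix(X)
  Z <- normalize_features(X, xref)
  R <- build_reference_set(Z)
  ext <- compute_extrema(Z, R)
  structure(list(feature_order = FEATURE_ORDER, xref = xref, R = R,
                 minAbs = unname(ext["minAbs"]),
                 maxAbs = unname(ext["maxAbs"]),
                 gamma = gamma,
                 weights = stats::setNames(weights, FEATURE_ORDER),
                 n_train = nrow(X),
                 training_subject_ids = subject_ids,
                 call = match.call()),
            class = "gait_grm")
}

#' Grey relational coefficients of one normalized row
#'
#' \deqn{\xi(j) = \frac{minAbs + \gamma\, maxAbs}
#'                     {|Z(j) - R(j)| + \gamma\, maxAbs}}
#' For test rows the deviation can fall below the training minAbs, which
#' would push the raw coefficient above 1; the deviation is therefore
#' floored at minAbs so that the coefficient (and hence every score)
#' stays in `[0, 1]`. Raw unclamped values are returned alongside for
#' audit.
#'
#' @param z_row normalized feature row.
#' @param model a fitted `gait_grm`.
#' @return list with `xi` (clamped) and `xi_raw`.
#' @export
correlation_coefficients <- function(z_row, model) {
  dev <- abs(z_row - model$R)
  if (model$maxAbs == 0) {
    warning("degenerate training (maxAbs = 0); coefficients are 0/1")
    xi <- as.numeric(dev == 0)
    return(list(xi = xi, xi_raw = xi))
  }
  scale <- model$minAbs + model$gamma * model$maxAbs
  xi_raw <- scale / (dev + model$gamma * model$maxAbs)
  xi <- scale / (pmax(dev, model$minAbs) + model$gamma * model$maxAbs)
  list(xi = unname(xi), xi_raw = unname(xi_raw))
}

#' Weighted grey correlation degree
#'
#' @param xi grey relational coefficients of one row.
#' @param weights feature weights summing to 1.
#' @return Ci in `[0, 1]` when `xi` is clamped.
#' @export
correlation_degree <- function(xi, weights) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  sum(weights * xi)
}

#' Score a subject's feature matrix against a fitted model
#'
#' Normalizes the test rows (one per AGG, nominally four) by the model's
#' reference matrix, computes the grey relational coefficient of every
#' feature and the weighted correlation degree Ci of every row, and
#' reports `Score = mean(Ci) * 100` on the 0-100 scale. Fewer than four
#' rows are averaged with a warning.
#'
#' @param object a fitted `gait_grm`.
#' @param newdata numeric matrix (or data.frame) of AGG-level feature
#'   vectors, columns (P, V, N, H, S).
#' @param ... unused.
#' @return an object of class `gait_assessment`: list with `score`,
#'   `Ci`, `xi`, `xi_raw`, `Z`.
#' @export
predict.gait_grm <- function(object, newdata, ...) {
  G <- as.matrix(newdata)
  if (is.null(colnames(G))) colnames(G) <- object$feature_order
  if (!all(object$feature_order %in% colnames(G)))
    stop("feature columns must be ", paste(object$feature_order,
                                           collapse = ", "))
  G <- G[, object$feature_order, drop = FALSE]
  if (nrow(G) < 4)
    warning("fewer than 4 AGG rows; score averaged over ", nrow(G))
  Z <- normalize_features(G, object$xref)
  res <- apply(Z, 1L, correlation_coefficients, model = object,
               simplify = FALSE)
  xi <- do.call(rbind, lapply(res, `[[`, "xi"))
  xi_raw <- do.call(rbind, lapply(res, `[[`, "xi_raw"))
  colnames(xi) <- colnames(xi_raw) <- object$feature_order
  Ci <- apply(xi, 1L, correlation_degree, weights = object$weights)
  structure(list(score = mean(Ci) * 100, Ci = unname(Ci),
                 xi = xi, xi_raw = xi_raw, Z = Z),
            class = "gait_assessment")
}

#' @export
print.gait_grm <- function(x, ...) {
  cat("Grey relational gait assessment model\n")
  cat(sprintf("  trained on %d AGG-level feature rows\n", x$n_train))
  cat("  Xref:", paste(sprintf("%s=%.4g", x$feature_order, x$xref),
                       collapse = ", "), "\n")
  cat(sprintf("  minAbs = %.4g, maxAbs = %.4g, gamma = %g\n",
              x$minAbs, x$maxAbs, x$gamma))
  invisible(x)
}

#' @export
summary.gait_grm <- function(object, ...) {
  out <- data.frame(feature = object$feature_order,
                    Xref = unname(object$xref),
                    R = unname(object$R),
                    weight = unname(object$weights))
  cat("Grey relational gait assessment model\n\n")
  print(out, row.names = FALSE)
  cat(sprintf("\nminAbs = %.4g, maxAbs = %.4g, gamma = %g, %d training rows\n",
              object$minAbs, object$maxAbs, object$gamma, object$n_train))
  invisible(out)
}

#' @export
coef.gait_grm <- function(object, ...) {
  rbind(Xref = object$xref, R = object$R, weight = object$weights)
}

#' @export
print.gait_assessment <- function(x, ...) {
  cat(sprintf("Gait assessment score: %.2f / 100\n", x$score))
  cat("  per-AGG correlation degrees:",
      paste(sprintf("%.3f", x$Ci), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `gait_grm` object.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_gait_model <- function(model, path) {
  payload <- list(feature_order = model$feature_order,
                  Xref = unname(model$xref), R = unname(model$R),
                  minAbs = model$minAbs, maxAbs = model$maxAbs,
                  gamma = model$gamma, weights = unname(model$weights),
                  n_train = model$n_train,
                  training_subject_ids = model$training_subject_ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path JSON path written by [write_gait_model()].
#' @return a `gait_grm` object.
#' @export
read_gait_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_order = p$feature_order,
                 xref = stats::setNames(p$Xref, p$feature_order),
                 R = stats::setNames(p$R, p$feature_order),
                 minAbs = p$minAbs, maxAbs = p$maxAbs, gamma = p$gamma,
                 weights = stats::setNames(p$weights, p$feature_order),
                 n_train = p$n_train,
                 training_subject_ids = p$training_subject_ids,
                 call = NULL),
            class = "gait_grm")
}
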