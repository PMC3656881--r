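# Regularized polynomial-kernel support vector classifier.
#
# Training is delegated to the libsvm solver (via e1071); the fitted model is
# reduced to its support vectors, dual coefficients and bias, and decision
# values are always recomputed from that kernel expansion
#   f(x) = sum_i alpha_i y_i (x_i . x + c0)^d + b
# so that serialized models are self-contained and bit-reproducible.

#' Polynomial kernel
#'
#' `(x . z + coef0)^degree`. With `degree = 1`, `coef0 = 0` this reduces to
#' the plain dot product; `degree = d` makes the implicit feature space span
#' all monomials of the inputs up to degree d, which is how interactions
#' between ligand positions enter the model without enumerating them.
#'
#' @param x,z numeric vectors of equal length.
#' @param degree polynomial degree (>= 1).
#' @param coef0 kernel offset (default 1, inhomogeneous kernel).
#' @return kernel value.
#' @examples
#' poly_kernel(c(1, 0), c(1, 0), degree = 2)  # 4
#' @export
poly_kernel <- function(x, z, degree = 2L, coef0 = 1) {
  if (length(x) != length(z))
    stop("x and z must have the same length (", length(x), " vs ",
         length(z), ")")
  (sum(x * z) + coef0)^degree
}

#' Number of monomials of a given degree
#'
#' Counts the distinct monomials in `n_dims` variables: `choose(n_dims +
#' degree - 1, degree)` of exact degree `degree`, or the cumulative count for
#' all degrees up to `degree` (the dimension of the inhomogeneous polynomial
#' kernel's feature space). For the 120-dimensional peptide encoding and
#' degree 3 this is 295240 exact-degree monomials, i.e. an implicit feature
#' space on the order of 3e5 dimensions.
#'
#' @param n_dims number of input dimensions (>= 1).
#' @param degree monomial degree (>= 0).
#' @param cumulative count all degrees `0..degree` instead of exact degree.
#' @return integer-valued count (double to avoid overflow).
#' @examples
#' monomial_count(2, 2)    # 3: x^2, y^2, xy
#' monomial_count(120, 3)  # 295240
#' @export
monomial_count <- function(n_dims, degree, cumulative = FALSE) {
  stopifnot(n_dims >= 1, degree >= 0)
  if (cumulative)
    sum(vapply(0:degree, function(d) choose(n_dims + d - 1, d), numeric(1)))
  else
    choose(n_dims + degree - 1, degree)
}

#' Train a polynomial-kernel SVM
#'
#' Fits a soft-margin C-classification SVM with kernel
#' `(x . z + coef0)^degree` on encoded peptides. Inputs are binary one-hot
#' encodings, so no feature scaling is applied. Training is deterministic for
#' fixed inputs; the stored model keeps only support vectors, dual
#' coefficients, bias and kernel configuration.
#'
#' @param x encoded instance matrix (rows = peptides).
#' @param y labels: +1/-1 numeric (or logical, TRUE = binding).
#' @param degree polynomial degree.
#' @param cost soft-margin cost parameter C.
#' @param coef0 kernel offset (default 1).
#' @param scheme optional encoding-scheme tag stored with the model and
#'   checked at prediction time.
#' @param tolerance optimizer termination tolerance.
#' @return object of class `sh2_svm`.
#' @export
svm_train <- function(x, y, degree = 2L, cost = 1, coef0 = 1,
                      scheme = NULL, tolerance = 1e-3) {
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "polynomial",
                    degree = degree, gamma = 1, coef0 = coef0, cost = cost,
                    scale = FALSE, tolerance = tolerance)
  # libsvm's decision value is positive for the class it encountered first;
  # normalize so positive values always mean the binding class
  dv1 <- attr(stats::predict(fit, x[1L, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  flip <- if (startsWith(colnames(dv1)[1], "pos")) 1 else -1
  structure(list(
    SV = unname(as.matrix(fit$SV)),
    coefs = as.vector(fit$coefs),
    rho = fit$rho,
    flip = flip,
    degree = as.integer(degree), cost = cost, coef0 = coef0,
    scheme = scheme, n_train = nrow(x), tolerance = tolerance),
    class = "sh2_svm")
}

#' @export
print.sh2_svm <- function(x, ...) {
  cat("<sh2_svm> degree=", x$degree, " cost=", x$cost, " coef0=", x$coef0,
      ", ", nrow(x$SV), " support vectors, trained on ", x$n_train,
      " instances", if (!is.null(x$scheme)) paste0(" [", x$scheme, "]"),
      "\n", sep = "")
  invisible(x)
}

#' SVM decision values
#'
#' Evaluates the kernel-expansion decision function on encoded peptides.
#' Positive values predict binding; the magnitude is the (unnormalized)
#' distance from the separating hyperplane, used as a confidence by the
#' rebalancing and scanning stages.
#'
#' @param model an `sh2_svm`.
#' @param x encoded matrix (or single vector) with the model's input
#'   dimensionality.
#' @param scheme optional encoding-scheme tag of `x`; must match the model's
#'   when both are set.
#' @return numeric decision values.
#' @export
decision_value <- function(model, x, scheme = NULL) {
  stopifnot(inherits(model, "sh2_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.null(scheme) && !is.null(model$scheme) && scheme != model$scheme)
    stop("encoding scheme mismatch: model '", model$scheme,
         "' vs input '", scheme, "'")
  if (ncol(x) != ncol(model$SV))
    stop("input has ", ncol(x), " columns; model expects ", ncol(model$SV))
  K <- (x %*% t(model$SV) + model$coef0)^model$degree
  model$flip * (as.vector(K %*% model$coefs) - model$rho)
}

#' @rdname decision_value
#' @return `svm_predict` returns +1/-1 labels (decision value >= 0 is +1).
#' @export
svm_predict <- function(model, x, scheme = NULL) {
  ifelse(decision_value(model, x, scheme) >= 0, 1L, -1L)
}

# explicit primal weights for a linear (degree-1, coef0 = 0) model:
# w = sum_i alpha_i y_i x_i, b = -rho (up to the sign normalization)
primal_weights <- function(model) {
  stopifnot(inherits(model, "sh2_svm"), model$degree == 1L, model$coef0 == 0)
  list(w = model$flip * as.vector(t(model$SV) %*% model$coefs),
       b = -model$flip * model$rho)
}

#' Serialize / restore an SVM model
#'
#' Models are written as versioned JSON containers holding the kernel
#' configuration, encoding scheme, support vectors, dual coefficients and
#' bias at full numeric precision, so reloaded models reproduce decision
#' values exactly. Loaders refuse files written by a newer major schema.
#'
#' @param model an `sh2_svm`.
#' @param path file path.
#' @return `load_model` returns the restored `sh2_svm`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sh2_svm"))
  payload <- list(
    schema = "sh2pep-model/1.0",
    degree = model$degree, cost = model$cost, coef0 = model$coef0,
    rho = model$rho, flip = model$flip, scheme = model$scheme,
    n_train = model$n_train, tolerance = model$tolerance,
    coefs = model$coefs, SV = model$SV)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- payload$schema
  if (is.null(schema) || !startsWith(schema, "sh2pep-model/"))
    stop("not an sh2pep model file: ", path)
  major <- as.integer(strsplit(sub("sh2pep-model/", "", schema), "[.]")[[1]][1])
  if (major > 1L)
    stop("model file ", path, " uses schema ", schema,
         "; this package reads majors <= 1")
  structure(list(
    SV = matrix(as.numeric(payload$SV), nrow = length(payload$coefs)),
    coefs = as.numeric(payload$coefs),
    rho = as.numeric(payload$rho), flip = as.numeric(payload$flip),
    degree = as.integer(payload$degree), cost = as.numeric(payload$cost),
    coef0 = as.numeric(payload$coef0),
    scheme = if (is.null(payload$scheme)) NULL else payload$scheme,
    n_train = as.integer(payload$n_train),
    tolerance = as.numeric(payload$tolerance)),
    class = "sh2_svm")
}
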