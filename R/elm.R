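#' Extreme learning machine configuration
#'
#' @param n_hidden number of hidden neurons `L` (>= 1).
#' @param activation hidden-layer activation; only `"sigmoid"` is supported.
#' @param weight_low,weight_high bounds of the uniform distribution the random
#'   input weights and biases are drawn from (defaults -1 and 1); these bounds
#'   also define the metaheuristic search box.
#' @param ridge optional ridge penalty added to the normal equations when
#'   solving for the output weights; 0 (default) uses the plain Moore-Penrose
#'   least-squares solution.
#' @param seed optional integer seed for the random hidden parameters.
#' @return An object of class `elm_config`.
#' @export
elm_config <- function(n_hidden, activation = "sigmoid",
                       weight_low = -1, weight_high = 1,
                       ridge = 0, seed = NULL) {
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  activation <- match.arg(activation, "sigmoid")
  if (!(weight_low < weight_high)) stop("weight_low must be < weight_high")
  if (ridge < 0) stop("ridge must be >= 0")
  structure(list(n_hidden = as.integer(n_hidden), activation = activation,
                 weight_low = weight_low, weight_high = weight_high,
                 ridge = ridge, seed = seed),
            class = "elm_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Hidden-layer activation matrix
#'
#' Computes `H[i, j] = sigma(x_i . omega_j + b_j)` with the logistic sigmoid
#' `sigma(z) = 1 / (1 + exp(-z))`.
#'
#' @param x numeric matrix `n x d` of inputs (rows = samples).
#' @param omega numeric matrix `d x L` of input-to-hidden weights.
#' @param bias numeric vector of length `L` of hidden-neuron thresholds.
#' @return Numeric matrix `n x L`.
#' @export
hidden_activations <- function(x, omega, bias) {
  x <- as.matrix(x); omega <- as.matrix(omega)
  if (ncol(x) != nrow(omega))
    stop("feature count of x does not match rows of omega")
  if (length(bias) != ncol(omega))
    stop("bias length does not match the number of hidden neurons")
  sigmoid(sweep(x %*% omega, 2, bias, "+"))
}

one_hot <- function(labels, classes) {
  t_mat <- matrix(0, length(labels), length(classes))
  t_mat[cbind(seq_along(labels), match(labels, classes))] <- 1
  t_mat
}

#' Train an extreme learning machine classifier
#'
#' Hidden parameters (input weights `omega`, biases `b`) are drawn uniformly
#' from `[weight_low, weight_high]` unless supplied explicitly -- the hook the
#' metaheuristic optimisers use. Output weights are the least-squares solution
#' `beta = pinv(H) %*% T` against one-hot targets, via the Moore-Penrose
#' pseudo-inverse (SVD).
#'
#' @param x numeric matrix `n x d` of training inputs.
#' @param labels class label per row.
#' @param config an [elm_config()].
#' @param omega,bias optional fixed hidden parameters overriding the random
#'   draw (dimensions `d x L` and length `L`).
#' @param classes ordered vector of all class labels; defaults to the sorted
#'   unique training labels. Supply explicitly when a partition might miss a
#'   class.
#' @return An object of class `elm_model` with elements `omega`, `bias`,
#'   `beta`, `activation`, `class_labels`.
#' @export
elm_train <- function(x, labels, config, omega = NULL, bias = NULL,
                      classes = NULL) {
  x <- as.matrix(x)
  stopifnot(inherits(config, "elm_config"))
  if (!all(is.finite(x))) stop("training inputs contain non-finite values")
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes)) stop("labels contain classes absent from 'classes'")
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes")
  if (nrow(x) < k) stop("need at least as many samples as classes")
  d <- ncol(x); l <- config$n_hidden
  if (is.null(omega) || is.null(bias)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    if (is.null(omega))
      omega <- matrix(stats::runif(d * l, config$weight_low, config$weight_high), d, l)
    if (is.null(bias))
      bias <- stats::runif(l, config$weight_low, config$weight_high)
  }
  omega <- as.matrix(omega)
  if (nrow(omega) != d || ncol(omega) != l || length(bias) != l)
    stop("omega/bias dimensions inconsistent with the data and config")
  h <- hidden_activations(x, omega, bias)
  t_mat <- one_hot(labels, classes)
  beta <- if (config$ridge > 0) {
    solve(crossprod(h) + diag(config$ridge, l), crossprod(h, t_mat))
  } else {
    MASS::ginv(h) %*% t_mat
  }
  structure(list(omega = omega, bias = as.numeric(bias), beta = beta,
                 activation = config$activation, class_labels = classes),
            class = "elm_model")
}

#' Predict class labels with a trained ELM
#'
#' Scores are `H %*% beta`; the predicted class is the argmax over the output
#' columns, with ties broken toward the lowest class index.
#'
#' @param model an `elm_model` from [elm_train()].
#' @param x numeric matrix of inputs with the training feature count.
#' @return Vector of predicted class labels.
#' @export
elm_predict <- function(model, x) {
  stopifnot(inherits(model, "elm_model"))
  scores <- elm_scores(model, x)
  model$class_labels[max.col(scores, ties.method = "first")]
}

#' @rdname elm_predict
#' @export
elm_scores <- function(model, x) {
  stopifnot(inherits(model, "elm_model"))
  h <- hidden_activations(as.matrix(x), model$omega, model$bias)
  h %*% model$beta
}

#' Pack and unpack optimiser position vectors
#'
#' The metaheuristics search over a flat vector holding the ELM hidden
#' parameters: `omega` in column-major order followed by `bias`, so the
#' position length is `d * L + L`.
#'
#' @param omega numeric matrix `d x L`.
#' @param bias numeric vector of length `L`.
#' @return `pack_position()`: numeric vector of length `d * L + L`.
#' @export
pack_position <- function(omega, bias) {
  omega <- as.matrix(omega)
  if (length(bias) != ncol(omega))
    stop("bias length must equal the number of hidden neurons")
  c(as.numeric(omega), as.numeric(bias))
}

#' @rdname pack_position
#' @param position numeric vector of length `d * L + L`.
#' @param d number of input features.
#' @param l number of hidden neurons.
#' @return `unpack_position()`: list with `omega` (`d x L`) and `bias`
#'   (length `L`).
#' @export
unpack_position <- function(position, d, l) {
  if (length(position) != d * l + l)
    stop(sprintf("position length %d does not match d*L + L = %d",
                 length(position), d * l + l))
  list(omega = matrix(position[seq_len(d * l)], d, l),
       bias = position[d * l + seq_len(l)])
}

#' Serialise an ELM model to JSON
#'
#' Writes weights, biases and class labels to a single JSON file (full double
#' precision) so command-line runs are resumable.
#'
#' @param model an `elm_model`.
#' @param path output file path.
#' @export
write_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  obj <- list(d = nrow(model$omega), n_hidden = ncol(model$omega),
              omega = as.numeric(model$omega), bias = model$bias,
              beta = as.numeric(model$beta), k = ncol(model$beta),
              activation = model$activation, class_labels = model$class_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(omega = matrix(obj$omega, obj$d, obj$n_hidden),
                 bias = obj$bias,
                 beta = matrix(obj$beta, obj$n_hidden, obj$k),
                 activation = obj$activation,
                 class_labels = obj$class_labels),
            class = "elm_model")
}
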