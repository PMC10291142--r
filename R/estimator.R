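# Joint neural flux estimator.
#
# Each reaction module m gets a small fully connected network f_m mapping the
# log(FPKM+1) expression of its genes in sample j to a scalar flux.  All
# module networks are trained jointly by full-batch Adam on the three-term
# loss
#
#   L = sum_jk (influx_kj - outflux_kj)^2          (flux imbalance)
#     + sum_jm (Flux_mj - |Flux_mj|)^2             (non-negativity)
#     + lambda * sum_j (sum_m Flux_mj - TA_j)^2    (total-activity anchor)
#
# where TA_j is a per-sample surrogate of total metabolic activity that
# excludes the trivial all-zero solution.

#' Training configuration for the flux estimator
#'
#' @param lambda_scale Non-negative weight of the total-activity anchor term.
#' @param hidden_sizes Hidden layer widths of each module predictor (tanh
#'   activations, linear scalar output).
#' @param epochs Maximum number of full-batch Adam epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialization.
#' @param ta_mode `"metabolic_total"` (TA_j = summed expression of all network
#'   genes in sample j) or `"constant"`.
#' @param ta_constant Constant TA value (required and non-negative when
#'   `ta_mode = "constant"`).
#' @param convergence_tol Relative-change threshold of the total loss below
#'   which an epoch counts as converged.
#' @param patience Number of consecutive converged epochs before stopping.
#' @return A validated list of class `flux_training_config`.
#' @export
flux_training_config <- function(lambda_scale = 1, hidden_sizes = c(8L, 4L),
                                 epochs = 100L, learning_rate = 0.008,
                                 seed = 42L,
                                 ta_mode = c("metabolic_total", "constant"),
                                 ta_constant = NULL,
                                 convergence_tol = 1e-4, patience = 10L) {
  ta_mode <- match.arg(ta_mode)
  stopifnot(lambda_scale >= 0, all(hidden_sizes >= 1), epochs >= 0,
            learning_rate > 0, convergence_tol > 0, patience >= 1)
  if (ta_mode == "constant") {
    if (is.null(ta_constant) || ta_constant < 0)
      stop("ta_mode 'constant' requires a non-negative ta_constant", call. = FALSE)
  }
  structure(list(lambda_scale = lambda_scale,
                 hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), ta_mode = ta_mode,
                 ta_constant = ta_constant,
                 convergence_tol = convergence_tol,
                 patience = as.integer(patience)),
            class = "flux_training_config")
}

#' Per-sample total metabolic activity surrogate
#'
#' @param expression Genes x samples matrix on the log(FPKM+1) scale.
#' @param graph A `factor_graph`; only genes in the graph's module rosters
#'   contribute.
#' @param mode `"metabolic_total"` or `"constant"`.
#' @param constant Value used when `mode = "constant"` (must be >= 0).
#' @return Named numeric vector of length `ncol(expression)`.
#' @export
total_activity <- function(expression, graph,
                           mode = c("metabolic_total", "constant"),
                           constant = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(constant) || constant < 0)
      stop("constant TA must be supplied and non-negative", call. = FALSE)
    return(stats::setNames(rep(constant, ncol(expression)), colnames(expression)))
  }
  genes <- intersect(rownames(expression), network_genes(graph))
  if (length(genes) == 0L)
    stop("expression matrix shares no genes with the graph", call. = FALSE)
  ta <- colSums(expression[genes, , drop = FALSE])
  if (any(ta == 0))
    warning("total activity is zero for ", sum(ta == 0), " sample(s)")
  ta
}

#' Evaluate the three-term flux loss
#'
#' Pure function of its inputs: returns the flux-imbalance term over the
#' graph's intermediate metabolites, the non-negativity penalty, the
#' lambda-weighted total-activity anchor, and their sum.
#'
#' @param flux Samples x modules flux matrix, columns aligned to the graph.
#' @param graph A validated `factor_graph`.
#' @param ta Per-sample total-activity values (length = rows of `flux`).
#' @param lambda_scale Non-negative anchor weight.
#' @return List with `total`, `balance`, `nonneg`, `scale`.
#' @export
compute_loss <- function(flux, graph, ta, lambda_scale = 1) {
  flux <- as.matrix(flux)
  if (ncol(flux) != graph$M)
    stop("flux has ", ncol(flux), " columns but the graph has ", graph$M,
         " modules", call. = FALSE)
  if (length(ta) != nrow(flux))
    stop("ta has length ", length(ta), " but flux has ", nrow(flux), " rows",
         call. = FALSE)
  if (!is.null(colnames(flux)) &&
      !identical(colnames(flux), names(graph$modules)))
    flux <- flux[, names(graph$modules), drop = FALSE]
  S <- incidence_matrix(graph)
  balance <- sum((flux %*% t(S))^2)
  nonneg <- sum((flux - abs(flux))^2)
  scale <- lambda_scale * sum((rowSums(flux) - ta)^2)
  list(total = balance + nonneg + scale,
       balance = balance, nonneg = nonneg, scale = scale)
}

# ---- network internals -----------------------------------------------------

init_module_net <- function(n_in, hidden_sizes) {
  sizes <- c(n_in, hidden_sizes, 1L)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))),
                 fan_in, fan_out),
      b = rep(0, fan_out))
  }
  layers
}

# forward pass; returns scalar output column and the activation stack
forward_module <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  n_l <- length(layers)
  A <- X
  for (l in seq_len(n_l)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    A <- if (l < n_l) tanh(Z) else Z
    acts[[l + 1L]] <- A
  }
  list(out = A[, 1L], acts = acts)
}

# gradients of the per-module network given dL/d(output) as a column vector
backward_module <- function(layers, acts, g_out) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  delta <- matrix(g_out, ncol = 1L)
  for (l in rev(seq_len(n_l))) {
    A_prev <- acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (l > 1L) {
      dA <- delta %*% t(layers[[l]]$W)
      delta <- dA * (1 - acts[[l]]^2)  # tanh'
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    st[[l]]$mW <- beta1 * st[[l]]$mW + (1 - beta1) * grads[[l]]$W
    st[[l]]$vW <- beta2 * st[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
    st[[l]]$mb <- beta1 * st[[l]]$mb + (1 - beta1) * grads[[l]]$b
    st[[l]]$vb <- beta2 * st[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (st[[l]]$mW / c1) /
      (sqrt(st[[l]]$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (st[[l]]$mb / c1) /
      (sqrt(st[[l]]$vb / c2) + eps)
  }
  list(layers = layers, state = st)
}

# assemble per-module design matrices (samples x module genes), zero-filling
# genes absent from the expression matrix
module_inputs <- function(graph, expression, warn = TRUE) {
  n <- ncol(expression)
  out <- lapply(graph$modules, function(m) {
    X <- matrix(0, nrow = n, ncol = length(m$genes),
                dimnames = list(colnames(expression), m$genes))
    present <- intersect(m$genes, rownames(expression))
    if (length(present))
      X[, present] <- t(expression[present, , drop = FALSE])
    attr(X, "n_present") <- length(present)
    X
  })
  missing_n <- sum(vapply(graph$modules, function(m)
    length(setdiff(m$genes, rownames(expression))), integer(1)))
  if (warn && missing_n > 0)
    warning(missing_n, " module gene(s) absent from the expression matrix; ",
            "imputed as zero expression")
  out
}

#' Train the joint neural flux model
#'
#' Fits one fully connected predictor per reaction module (shared
#' architecture from the config) by full-batch Adam on the joint three-term
#' loss.  Modules none of whose genes appear in the expression matrix are
#' pinned to zero flux with a warning.  Training stops after
#' `config$epochs` epochs or once the relative change of the total loss
#' stays below `config$convergence_tol` for `config$patience` consecutive
#' epochs; the run is deterministic given `config$seed`.
#'
#' @param graph A validated `factor_graph`.
#' @param expression Genes x samples matrix on the log(FPKM+1) scale
#'   (non-negative).
#' @param config A [flux_training_config()].
#' @return A list of class `flux_fit` with elements `model` (a `flux_model`
#'   usable with [predict_flux()]), `flux` (samples x modules matrix of final
#'   training-set predictions), and `trace` (epoch-indexed data.frame of the
#'   loss terms).
#' @export
train_flux_model <- function(graph, expression, config = flux_training_config()) {
  stopifnot(inherits(config, "flux_training_config"))
  expression <- as.matrix(expression)
  if (min(expression) < 0)
    stop("expression must be non-negative (log(FPKM+1) scale)", call. = FALSE)
  if (length(intersect(rownames(expression), network_genes(graph))) == 0L)
    stop("expression matrix shares no genes with the graph", call. = FALSE)

  X <- module_inputs(graph, expression)
  pinned <- vapply(X, function(x) attr(x, "n_present") == 0L, logical(1))
  if (any(pinned))
    warning("module(s) with no observed genes pinned to zero flux: ",
            paste(names(which(pinned)), collapse = ", "))
  active <- which(!pinned)
  ta <- total_activity(expression, graph, mode = config$ta_mode,
                       constant = config$ta_constant)
  S <- incidence_matrix(graph)
  n <- ncol(expression); M <- graph$M
  lambda <- config$lambda_scale

  set.seed(config$seed)
  nets <- lapply(graph$modules, function(m)
    init_module_net(length(m$genes), config$hidden_sizes))
  opt <- lapply(nets, adam_state)

  F <- matrix(0, n, M, dimnames = list(colnames(expression), names(graph$modules)))
  fwd <- vector("list", M)
  forward_all <- function() {
    for (m in active) {
      fwd[[m]] <<- forward_module(nets[[m]], X[[m]])
      F[, m] <<- fwd[[m]]$out
    }
  }
  loss_terms <- function() {
    balance <- sum((F %*% t(S))^2)
    nonneg <- sum((F - abs(F))^2)
    scale <- lambda * sum((rowSums(F) - ta)^2)
    c(total = balance + nonneg + scale, balance = balance,
      nonneg = nonneg, scale = scale)
  }

  forward_all()
  trace <- list(c(epoch = 0, loss_terms()))
  prev_total <- trace[[1]][["total"]]
  stall <- 0L
  epochs_run <- 0L

  for (ep in seq_len(config$epochs)) {
    # dL/dF
    gF <- 2 * (F %*% t(S)) %*% S                        # imbalance
    gF <- gF + ifelse(F < 0, 8 * F, 0)                  # non-negativity
    gF <- gF + 2 * lambda * (rowSums(F) - ta)           # anchor (same for all m)
    for (m in active) {
      grads <- backward_module(nets[[m]], fwd[[m]]$acts, gF[, m])
      upd <- adam_step(nets[[m]], grads, opt[[m]], config$learning_rate, ep)
      nets[[m]] <- upd$layers
      opt[[m]] <- upd$state
    }
    forward_all()
    lt <- loss_terms()
    if (!all(is.finite(lt)))
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    trace[[length(trace) + 1L]] <- c(epoch = ep, lt)
    rel <- abs(lt[["total"]] - prev_total) / max(abs(prev_total), 1e-12)
    stall <- if (rel < config$convergence_tol) stall + 1L else 0L
    prev_total <- lt[["total"]]
    epochs_run <- ep
    if (stall >= config$patience) break
  }

  trace <- as.data.frame(do.call(rbind, trace))
  model <- structure(list(
    nets = nets,
    genes = lapply(graph$modules, `[[`, "genes"),
    pinned = pinned,
    module_ids = names(graph$modules),
    config = config,
    epochs_run = epochs_run
  ), class = "flux_model")
  neg_frac <- mean(F < -1e-8)
  structure(list(model = model, flux = F, trace = trace,
                 negative_fraction = neg_frac),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat("Flux fit: ", nrow(x$flux), " samples x ", ncol(x$flux), " modules; ",
      x$model$epochs_run, " epochs\n", sep = "")
  cat(sprintf("Final loss %.4g (balance %.4g, nonneg %.4g, scale %.4g); %.2f%% entries < -1e-8\n",
              last$total, last$balance, last$nonneg, last$scale,
              100 * x$negative_fraction))
  invisible(x)
}

#' Predict sample-wise fluxes with a trained model
#'
#' Applies each module predictor to the sample's gene vector, resolving genes
#' by name and zero-filling genes absent from the new matrix (with a
#' warning).  No retraining occurs.
#'
#' @param model A `flux_model` from [train_flux_model()].
#' @param expression Genes x samples matrix.
#' @param clamp If `TRUE`, clamp predictions at zero for reporting (default
#'   `FALSE`: non-negativity is encouraged only through the training loss).
#' @return Samples x modules flux matrix.
#' @export
predict_flux <- function(model, expression, clamp = FALSE) {
  stopifnot(inherits(model, "flux_model"))
  expression <- as.matrix(expression)
  n <- ncol(expression)
  F <- matrix(0, n, length(model$module_ids),
              dimnames = list(colnames(expression), model$module_ids))
  missing_n <- 0L
  for (m in seq_along(model$module_ids)) {
    if (model$pinned[[m]]) next
    genes <- model$genes[[m]]
    X <- matrix(0, nrow = n, ncol = length(genes))
    present <- intersect(genes, rownames(expression))
    missing_n <- missing_n + length(genes) - length(present)
    if (length(present))
      X[, match(present, genes)] <- t(expression[present, , drop = FALSE])
    F[, m] <- forward_module(model$nets[[m]], X)$out
  }
  if (missing_n > 0)
    warning(missing_n, " model gene(s) absent from the expression matrix; zero-filled")
  if (clamp) F[F < 0] <- 0
  F
}

#' Metabolite abundance-change surrogate (influx minus outflux)
#'
#' For each sample and each intermediate metabolite, the difference between
#' total producing and total consuming flux; positive values indicate
#' predicted accumulation, negative values depletion.
#'
#' @param flux Samples x modules flux matrix.
#' @param graph A validated `factor_graph`.
#' @return Samples x intermediates matrix (the balance profile).
#' @export
metabolite_change <- function(flux, graph) {
  flux <- as.matrix(flux)
  if (ncol(flux) != graph$M)
    stop("flux has ", ncol(flux), " columns but the graph has ", graph$M,
         " modules", call. = FALSE)
  if (!is.null(colnames(flux)) &&
      !identical(colnames(flux), names(graph$modules)))
    flux <- flux[, names(graph$modules), drop = FALSE]
  S <- incidence_matrix(graph)
  flux %*% t(S)
}
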