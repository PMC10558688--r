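# Minimal dense/convolutional network core with analytic backpropagation.
# Everything is plain R arrays and BLAS matrix products: 3x3 (and 3x3x3)
# convolutions are evaluated as shift-and-accumulate matrix multiplies,
# which keeps the whole training loop deterministic on CPU and lets the
# attribution code backpropagate exactly to the inputs. Tensors are stored
# channels-last: 2D batches are [N, H, W, C], 3D batches [N, D1, D2, D3, C].

he_init <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)

pad2 <- function(X) {
  d <- dim(X)
  out <- array(0, d + c(0, 2, 2, 0))
  out[, 2:(d[2] + 1), 3:(d[3] + 2) - 1, ] <- X
  out
}

conv2_fw <- function(X, W, b)
  .conv2_fw_cpp(X, dim(X), W, b)

conv2_bw <- function(X, W, dY)
  .conv2_bw_cpp(X, dim(X), W, dim(W), dY)

conv3_fw <- function(X, W, b)
  .conv3_fw_cpp(X, dim(X), W, b)

conv3_bw <- function(X, W, dY)
  .conv3_bw_cpp(X, dim(X), W, dim(W), dY)

# Plain-R reference implementations of the convolutions (shift-accumulate
# as BLAS matrix products); kept as an independent oracle for the compiled
# kernels in the test suite.
conv2_fw_ref <- function(X, W, b) {
  d <- dim(X); co <- dim(W)[4]
  Xp <- pad2(X)
  acc <- matrix(rep(b, each = d[1] * d[2] * d[3]), ncol = co)
  for (i in 1:3) for (j in 1:3) {
    Xs <- Xp[, i:(i + d[2] - 1), j:(j + d[3] - 1), , drop = FALSE]
    acc <- acc + matrix(Xs, ncol = d[4]) %*% matrix(W[i, j, , ], d[4], co)
  }
  array(acc, dim = c(d[1:3], co))
}

conv2_bw_ref <- function(X, W, dY) {
  d <- dim(X); co <- dim(W)[4]
  Xp <- pad2(X)
  dYm <- matrix(dY, ncol = co)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(Xp))
  for (i in 1:3) for (j in 1:3) {
    Xs <- Xp[, i:(i + d[2] - 1), j:(j + d[3] - 1), , drop = FALSE]
    dW[i, j, , ] <- t(matrix(Xs, ncol = d[4])) %*% dYm
    dXs <- dYm %*% t(matrix(W[i, j, , ], d[4], co))
    dXp[, i:(i + d[2] - 1), j:(j + d[3] - 1), ] <-
      dXp[, i:(i + d[2] - 1), j:(j + d[3] - 1), , drop = FALSE] +
      array(dXs, dim = c(d[1:3], d[4]))
  }
  list(dX = dXp[, 2:(d[2] + 1), 2:(d[3] + 1), , drop = FALSE], dW = dW,
       db = colSums(dYm))
}

pad3 <- function(X) {
  d <- dim(X)
  out <- array(0, d + c(0, 2, 2, 2, 0))
  out[, 2:(d[2] + 1), 2:(d[3] + 1), 2:(d[4] + 1), ] <- X
  out
}

conv3_fw_ref <- function(X, W, b) {
  d <- dim(X); co <- dim(W)[5]
  Xp <- pad3(X)
  acc <- matrix(rep(b, each = prod(d[1:4])), ncol = co)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    Xs <- Xp[, i:(i + d[2] - 1), j:(j + d[3] - 1), k:(k + d[4] - 1), , drop = FALSE]
    acc <- acc + matrix(Xs, ncol = d[5]) %*% matrix(W[i, j, k, , ], d[5], co)
  }
  array(acc, dim = c(d[1:4], co))
}

conv3_bw_ref <- function(X, W, dY) {
  d <- dim(X); co <- dim(W)[5]
  Xp <- pad3(X)
  dYm <- matrix(dY, ncol = co)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(Xp))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    Xs <- Xp[, i:(i + d[2] - 1), j:(j + d[3] - 1), k:(k + d[4] - 1), , drop = FALSE]
    dW[i, j, k, , ] <- t(matrix(Xs, ncol = d[5])) %*% dYm
    dXs <- dYm %*% t(matrix(W[i, j, k, , ], d[5], co))
    dXp[, i:(i + d[2] - 1), j:(j + d[3] - 1), k:(k + d[4] - 1), ] <-
      dXp[, i:(i + d[2] - 1), j:(j + d[3] - 1), k:(k + d[4] - 1), , drop = FALSE] +
      array(dXs, dim = c(d[1:4], d[5]))
  }
  list(dX = dXp[, 2:(d[2] + 1), 2:(d[3] + 1), 2:(d[4] + 1), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

# 2x2 (2D) / 2x2x2 (3D) max pooling with stride 2; odd trailing rows/cols
# are dropped. Returns output, plus argmax bookkeeping for the backward pass.
pool_fw <- function(X, nd) {
  d <- dim(X)
  sp <- d[2:(1 + nd)]
  sp2 <- sp %/% 2L
  slices <- list(); combos <- expand.grid(rep(list(0:1), nd))
  idx <- lapply(seq_len(nd), function(ax) list(seq(1, 2 * sp2[ax], 2),
                                               seq(2, 2 * sp2[ax], 2)))
  Y <- NULL; claimed <- NULL; masks <- vector("list", nrow(combos))
  get_slice <- function(row) {
    if (nd == 2) X[, idx[[1]][[row[1] + 1]], idx[[2]][[row[2] + 1]], , drop = FALSE]
    else X[, idx[[1]][[row[1] + 1]], idx[[2]][[row[2] + 1]],
           idx[[3]][[row[3] + 1]], , drop = FALSE]
  }
  for (r in seq_len(nrow(combos))) {
    s <- get_slice(as.integer(combos[r, ]))
    Y <- if (is.null(Y)) s else pmax(Y, s)
  }
  for (r in seq_len(nrow(combos))) {
    s <- get_slice(as.integer(combos[r, ]))
    m <- (s == Y)
    if (is.null(claimed)) claimed <- array(FALSE, dim(m))
    m <- m & !claimed
    claimed <- claimed | m
    masks[[r]] <- m
  }
  list(Y = Y, masks = masks, combos = combos, idx = idx, in_dim = d)
}

pool_bw <- function(cache, dY, nd) {
  dX <- array(0, cache$in_dim)
  for (r in seq_len(nrow(cache$combos))) {
    row <- as.integer(cache$combos[r, ])
    g <- dY * cache$masks[[r]]
    if (nd == 2) {
      dX[, cache$idx[[1]][[row[1] + 1]], cache$idx[[2]][[row[2] + 1]], ] <- g
    } else {
      dX[, cache$idx[[1]][[row[1] + 1]], cache$idx[[2]][[row[2] + 1]],
         cache$idx[[3]][[row[3] + 1]], ] <- g
    }
  }
  dX
}

#' Capacity ladder of the convolutional backbone family
#'
#' Six compound-scaled variants C1-C6 with strictly increasing parameter
#' count (wider and deeper together), standing in for an ImageNet-scale
#' family at desk scale.
#'
#' @param capacity integer 1-6.
#' @return list with `width` (base channels) and `depth` (conv blocks).
#' @export
capacity_settings <- function(capacity) {
  stopifnot(capacity >= 1, capacity <= 6)
  list(width = c(8L, 10L, 13L, 16L, 20L, 24L)[capacity],
       depth = c(2L, 2L, 3L, 3L, 4L, 4L)[capacity])
}

#' Build the configurable multi-task network
#'
#' Convolutional backbone (2D for 2.5D slice inputs, 3D for volume inputs)
#' at the requested capacity, global average pooling, and a fully connected
#' head. Task heads are always present; auxiliary prior-regression heads are
#' added for integration levels `AuxLosses` and `AuxLosses@Branches`; the
#' prior values are concatenated into the final fully connected layer for
#' `Branches` and `AuxLosses@Branches`.
#'
#' @param config a [trial_configuration()].
#' @param n_tasks,n_priors head counts.
#' @param input_shape spatial+channel shape of one sample (e.g. `c(H, W, 3)`).
#' @param seed initialization seed.
#' @return list of class `fiber_model` (architecture, parameters, head
#'   metadata, learnable log-sigmas).
#' @export
build_model <- function(config, n_tasks, n_priors, input_shape, seed = 1) {
  if (config$prior_integration == "PriorsOnly")
    stop("PriorsOnly configurations use the feature pipeline, not a network")
  nd <- length(input_shape) - 1
  stopifnot(nd %in% c(2, 3))
  caps <- capacity_settings(config$capacity)
  use_branch <- config$prior_integration %in% c("Branches", "AuxLosses@Branches")
  use_aux <- config$prior_integration %in% c("AuxLosses", "AuxLosses@Branches")
  n_out <- n_tasks + if (use_aux) n_priors else 0L

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  arch <- list()
  params <- list()
  cin <- input_shape[nd + 1]
  sp <- input_shape[1:nd]
  if (nd == 3 && min(sp) >= 8) {
    # stem pooling: volumes enter at half resolution, the standard economy
    # for volumetric backbones at this scale
    arch[[length(arch) + 1]] <- list(type = "pool3")
    sp <- sp %/% 2L
  }
  # desk-scale compound scaling: capacity grows the base width and depth
  # while per-network channel growth is capped at 2x; volumetric variants
  # additionally pool down to smaller grids (3x3x3 kernels already carry 3x
  # the parameters per channel pair)
  growth_cap <- 2
  pool_min <- if (nd == 3) 4 else 8
  for (b in seq_len(caps$depth)) {
    cout <- caps$width * min(2^(b - 1), growth_cap)
    wn <- paste0("conv", b, "_W"); bn <- paste0("conv", b, "_b")
    kdim <- if (nd == 2) c(3, 3, cin, cout) else c(3, 3, 3, cin, cout)
    params[[wn]] <- he_init(kdim, fan_in = 3^nd * cin)
    params[[bn]] <- rep(0, cout)
    arch[[length(arch) + 1]] <- list(type = paste0("conv", nd), W = wn, b = bn)
    arch[[length(arch) + 1]] <- list(type = "relu")
    if (min(sp) >= pool_min) {
      arch[[length(arch) + 1]] <- list(type = paste0("pool", nd))
      sp <- sp %/% 2L
    }
    cin <- cout
  }
  arch[[length(arch) + 1]] <- list(type = "gap")
  feat_dim <- cin + if (use_branch) n_priors else 0L
  hidden <- 2L * caps$width
  params$fc1_W <- he_init(c(feat_dim, hidden), fan_in = feat_dim)
  params$fc1_b <- rep(0, hidden)
  params$out_W <- he_init(c(hidden, n_out), fan_in = hidden)
  params$out_b <- rep(0, n_out)
  params$log_sigma <- rep(0, n_out)  # sigma = 1 at start

  structure(list(arch = arch, params = params, nd = nd,
                 n_tasks = n_tasks, n_priors = n_priors,
                 use_branch = use_branch, use_aux = use_aux,
                 n_out = n_out, config = config,
                 input_shape = input_shape),
            class = "fiber_model")
}

#' Number of trainable parameters of a model
#' @param model a `fiber_model`.
#' @return integer count (excluding the loss log-sigmas).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params[setdiff(names(model$params), "log_sigma")], length, 1L))
}

#' Forward pass
#'
#' @param model a `fiber_model` from [build_model()].
#' @param X batch array (`[N, H, W, C]` or `[N, D1, D2, D3, C]`).
#' @param priors `N x n_priors` matrix (required for branch integration).
#' @param keep_cache retain intermediate activations for [nn_backward()].
#' @return list with `out` (`N x n_out` raw scores) and `cache`.
#' @export
nn_forward <- function(model, X, priors = NULL, keep_cache = FALSE) {
  P <- model$params
  cache <- list(inputs = list())
  A <- X
  for (li in seq_along(model$arch)) {
    node <- model$arch[[li]]
    if (keep_cache) cache$inputs[[li]] <- A
    A <- switch(node$type,
      conv2 = conv2_fw(A, P[[node$W]], P[[node$b]]),
      conv3 = conv3_fw(A, P[[node$W]], P[[node$b]]),
      relu = pmax(A, 0),
      pool2 = { pc <- pool_fw(A, 2); if (keep_cache) cache$pool[[li]] <- pc; pc$Y },
      pool3 = { pc <- pool_fw(A, 3); if (keep_cache) cache$pool[[li]] <- pc; pc$Y },
      gap = { d <- dim(A); matrix(A, nrow = d[1]) %*%
          kronecker(diag(d[length(d)]), rep(1 / prod(d[-c(1, length(d))]),
                                            prod(d[-c(1, length(d))]))) })
    if (node$type == "gap" && keep_cache) cache$gap_in_dim <- dim(cache$inputs[[li]])
  }
  feat <- A
  if (model$use_branch) {
    stopifnot(!is.null(priors))
    feat <- cbind(feat, priors)
  }
  if (keep_cache) cache$feat <- feat
  h_pre <- sweep(feat %*% P$fc1_W, 2, P$fc1_b, `+`)
  h <- pmax(h_pre, 0)
  if (keep_cache) { cache$h_pre <- h_pre; cache$h <- h }
  out <- sweep(h %*% P$out_W, 2, P$out_b, `+`)
  list(out = out, cache = if (keep_cache) cache else NULL)
}

#' Backward pass
#'
#' @param model a `fiber_model`.
#' @param cache cache from [nn_forward()] with `keep_cache = TRUE`.
#' @param dOut gradient of the loss w.r.t. the raw output scores.
#' @param input_grad also backpropagate to the image input and prior branch.
#' @return list with `grads` (named like `model$params`), and when requested
#'   `dX` and `dPriors`.
#' @export
nn_backward <- function(model, cache, dOut, input_grad = FALSE) {
  P <- model$params
  G <- list()
  G$out_W <- t(cache$h) %*% dOut
  G$out_b <- colSums(dOut)
  dh <- dOut %*% t(P$out_W)
  dh <- dh * (cache$h_pre > 0)
  G$fc1_W <- t(cache$feat) %*% dh
  G$fc1_b <- colSums(dh)
  dfeat <- dh %*% t(P$fc1_W)
  dPriors <- NULL
  nf <- ncol(dfeat)
  if (model$use_branch) {
    np <- model$n_priors
    dPriors <- dfeat[, (nf - np + 1):nf, drop = FALSE]
    dfeat <- dfeat[, 1:(nf - np), drop = FALSE]
  }
  dA <- dfeat
  for (li in rev(seq_along(model$arch))) {
    node <- model$arch[[li]]
    A_in <- cache$inputs[[li]]
    dA <- switch(node$type,
      gap = {
        d <- cache$gap_in_dim
        nsp <- prod(d[-c(1, length(d))])
        big <- array(0, d)
        # broadcast dA/nsp over spatial positions
        arr <- aperm(array(rep(t(dA / nsp), nsp),
                           dim = c(d[length(d)], d[1], nsp)), c(2, 3, 1))
        array(arr, dim = d)
      },
      relu = dA * (A_in > 0),
      pool2 = pool_bw(cache$pool[[li]], dA, 2),
      pool3 = pool_bw(cache$pool[[li]], dA, 3),
      conv2 = {
        bw <- conv2_bw(A_in, P[[node$W]], dA)
        G[[node$W]] <- bw$dW; G[[node$b]] <- bw$db
        bw$dX
      },
      conv3 = {
        bw <- conv3_bw(A_in, P[[node$W]], dA)
        G[[node$W]] <- bw$dW; G[[node$b]] <- bw$db
        bw$dX
      })
    if (li == 1 && !input_grad) break
  }
  list(grads = G, dX = if (input_grad) dA else NULL, dPriors = dPriors)
}

#' Uncertainty-weighted masked multi-task loss
#'
#' Per-output base losses (binary cross-entropy with logits for
#' classification heads, squared error for regression and prior heads) are
#' combined as `sum_k (L_k / sigma_k^2 + log sigma_k)` over heads with at
#' least one unmasked entry; sigma is parameterized as `log sigma` so it
#' stays positive. Masked entries contribute exactly zero to the value and
#' to every gradient.
#'
#' @param pred `N x K` raw scores.
#' @param target `N x K` targets (0/1 for binary heads).
#' @param mask `N x K` logical, `TRUE` = supervised.
#' @param log_sigma length-K learnable log uncertainties.
#' @param types length-K character, `"binary"` or `"continuous"`.
#' @return list with `loss`, `base_losses` (per head, `NA` if fully masked),
#'   `dpred`, `dlog_sigma`, and `n_terms`.
#' @export
masked_uncertainty_loss <- function(pred, target, mask, log_sigma, types) {
  K <- ncol(pred)
  stopifnot(length(log_sigma) == K, length(types) == K)
  dpred <- matrix(0, nrow(pred), K)
  dls <- rep(0, K)
  base <- rep(NA_real_, K)
  total <- 0
  n_terms <- 0L
  for (k in seq_len(K)) {
    mk <- which(mask[, k])
    if (length(mk) == 0) next
    x <- pred[mk, k]; t <- target[mk, k]
    if (types[k] == "binary") {
      L <- mean(pmax(x, 0) - x * t + log1p(exp(-abs(x))))
      g <- (plogis(x) - t) / length(mk)
    } else {
      L <- mean((x - t)^2)
      g <- 2 * (x - t) / length(mk)
    }
    inv_s2 <- exp(-2 * log_sigma[k])
    total <- total + L * inv_s2 + log_sigma[k]
    dpred[mk, k] <- g * inv_s2
    dls[k] <- -2 * L * inv_s2 + 1
    base[k] <- L
    n_terms <- n_terms + 1L
  }
  list(loss = total, base_losses = base, dpred = dpred, dlog_sigma = dls,
       n_terms = n_terms)
}

make_optimizer <- function(name, lr, momentum = 0.9) {
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list(); state$t <- 0
  step <- function(params, grads, clip = NULL) {
    if (!is.null(clip)) {
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
      if (is.finite(gn) && gn > clip)
        grads <- lapply(grads, function(g) g * (clip / gn))
    }
    state$t <- state$t + 1
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (name == "sgd") {
        mprev <- state$m[[nm]] %||% (g * 0)
        state$m[[nm]] <- momentum * mprev - lr * g
        params[[nm]] <- params[[nm]] + state$m[[nm]]
      } else {  # adam
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        state$m[[nm]] <- b1 * (state$m[[nm]] %||% (g * 0)) + (1 - b1) * g
        state$v[[nm]] <- b2 * (state$v[[nm]] %||% (g * 0)) + (1 - b2) * g^2
        mh <- state$m[[nm]] / (1 - b1^state$t)
        vh <- state$v[[nm]] / (1 - b2^state$t)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    params
  }
  list(step = step, state = state)
}
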