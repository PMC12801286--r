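# Network architectures: gated-attention MIL (WSINet), the spatial-branch
# MLP (SpB), the morphological branch (MpB), two-branch multi-view fusion
# (MVNet) and clinical multi-modal fusion (MMF).
#
# Data convention: rows are instances/cases. All forwards are built on the
# autodiff tape so training and prediction share one code path.

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

init_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
init_bias <- function(k) numeric(k)

#' Gated-attention parameters
#'
#' Parameters of the simplified gated-attention network: two fully connected
#' embedding layers producing the per-instance feature f_i, gate matrices
#' W_a (tanh branch) and W_b (sigmoid branch), and the score matrix W.
#'
#' @param d_in instance feature width.
#' @param h embedding width (default 256).
#' @param a gate width (default 128).
#' @param seed RNG seed for the initialization.
#' @return Named list of parameter matrices.
#' @export
attention_params <- function(d_in, h = 256L, a = 128L, seed = 1L) {
  with_seed(seed, list(
    W1 = init_mat(d_in, h), b1 = init_bias(h),
    W2 = init_mat(h, h), b2 = init_bias(h),
    Wa = init_mat(h, a), Wb = init_mat(h, a),
    Ws = init_mat(a, 1L)
  ))
}

# gated-attention graph over a stacked instance matrix with case groups
ga_graph <- function(tape, pn, Xnode, groups) {
  f <- ad_relu(tape, ad_linear(tape, Xnode, pn$W1, pn$b1))
  f <- ad_relu(tape, ad_linear(tape, f, pn$W2, pn$b2))
  gate <- ad_mul(tape,
                 ad_tanh(tape, ad_matmul(tape, f, pn$Wa)),
                 ad_sigmoid(tape, ad_matmul(tape, f, pn$Wb)))
  raw <- ad_matmul(tape, gate, pn$Ws)
  S <- ad_group_softmax(tape, raw, groups)
  pooled <- ad_group_pool(tape, S, f, groups)
  list(S = S, pooled = pooled, f = f)
}

make_pnodes <- function(tape, params) {
  out <- lapply(names(params), function(nm) ad_param(tape, params[[nm]], nm))
  names(out) <- names(params)
  out
}

const_pnodes <- function(tape, params) {
  out <- lapply(params, function(p) ad_const(tape, p))
  names(out) <- names(params)
  out
}

pick <- function(pn, prefix) {
  sel <- startsWith(names(pn), paste0(prefix, "."))
  out <- pn[sel]
  names(out) <- sub(paste0("^", prefix, "\\."), "", names(out))
  out
}

#' Gated attention over an instance bag
#'
#' Computes the attention score of every instance,
#' \deqn{S_i = \mathrm{softmax}_i\!\big(W(\tanh(W_a f_i) \odot
#'   \sigma(W_b f_i))\big),}
#' where f_i is the instance embedding after two fully connected ReLU
#' layers, and the attention-pooled case feature \eqn{\sum_i S_i f_i}.
#' Scores form a probability vector over the bag.
#'
#' @param bag numeric matrix, one instance per row.
#' @param params an [attention_params()] list.
#' @return List with `scores` (length N, sums to 1), `pooled` (embedding-width
#'   vector) and `embedded` (N x h matrix of f_i).
#' @export
gated_attention <- function(bag, params) {
  bag <- as.matrix(bag)
  if (any(!is.finite(bag))) stop("bag contains non-finite values")
  if (ncol(bag) != nrow(params$W1)) stop("bag width does not match W1")
  tape <- ad_tape()
  pn <- const_pnodes(tape, params)
  g <- ga_graph(tape, pn, ad_const(tape, bag), rep(1L, nrow(bag)))
  list(scores = as.vector(g$S$value),
       pooled = as.vector(g$pooled$value),
       embedded = g$f$value)
}

#' WSINet: gated-attention MIL over patch-feature bags
#'
#' `wsinet_init` builds parameters for the case-level MIL classifier:
#' gated attention over all patch features of a case followed by a linear
#' two-class head on the pooled feature. `wsinet_forward` runs one case.
#'
#' @param d_p patch feature width (default 768).
#' @param h,a attention embedding and gate widths.
#' @param seed RNG seed.
#' @return `wsinet_init`: a model list; `wsinet_forward`: list with
#'   `prob` (2-vector, sums to 1), `scores`, `pooled`.
#' @export
wsinet_init <- function(d_p = 768L, h = 256L, a = 128L, seed = 1L) {
  att <- attention_params(d_p, h, a, seed)
  head <- with_seed(seed + 1L,
                    list(W = init_mat(h, 2L), b = init_bias(2L)))
  params <- c(stats::setNames(att, paste0("att.", names(att))),
              stats::setNames(head, paste0("head.", names(head))))
  structure(list(type = "wsinet", params = params,
                 config = list(d_p = d_p, h = h, a = a, seed = seed)),
            class = "tls_net")
}

#' @rdname wsinet_init
#' @param bag N x d_p patch feature matrix for one case.
#' @param model a `wsinet_init` model.
#' @export
wsinet_forward <- function(bag, model) {
  stopifnot(model$type == "wsinet")
  bag <- as.matrix(bag)
  if (any(!is.finite(bag))) stop("bag contains non-finite values")
  tape <- ad_tape()
  pn <- const_pnodes(tape, model$params)
  g <- ga_graph(tape, pick(pn, "att"), ad_const(tape, bag),
                rep(1L, nrow(bag)))
  logits <- ad_linear(tape, g$pooled, pn$head.W, pn$head.b)
  list(prob = as.vector(ad_softmax_rows(logits$value)),
       scores = as.vector(g$S$value),
       pooled = as.vector(g$pooled$value))
}

# ---- spatial branch (SpB) ----

mlp_params <- function(dims, seed) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(length(dims) - 1L)) {
      out[[paste0("W", i)]] <- init_mat(dims[i], dims[i + 1L])
      out[[paste0("b", i)]] <- init_bias(dims[i + 1L])
    }
    out
  })
}

#' SpB: the spatial-branch multi-layer perceptron
#'
#' Maps the standardized 226-dimensional spatial feature vector through a
#' 226 -> 128 -> 64 -> 32 ReLU MLP to the spatial representation r_S.
#'
#' @param d_in input width (default 226).
#' @param dims hidden/output widths (default `c(128, 64, 32)`).
#' @param seed RNG seed.
#' @return `spb_init`: model list; `spb_forward`: matrix of r_S rows.
#' @export
spb_init <- function(d_in = 226L, dims = c(128L, 64L, 32L), seed = 1L) {
  params <- mlp_params(c(d_in, dims), seed)
  names(params) <- paste0("spb.", names(params))
  structure(list(type = "spb", params = params,
                 config = list(d_in = d_in, dims = dims, seed = seed)),
            class = "tls_net")
}

spb_graph <- function(tape, pn, Xnode) {
  x <- Xnode
  nlayer <- sum(startsWith(names(pn), "W"))
  for (i in seq_len(nlayer))
    x <- ad_relu(tape, ad_linear(tape, x, pn[[paste0("W", i)]],
                                 pn[[paste0("b", i)]]))
  x
}

#' @rdname spb_init
#' @param x numeric vector of length 226 (standardized) or a matrix of such
#'   rows.
#' @param model an `spb_init` model (or any model embedding SpB parameters).
#' @export
spb_forward <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (any(!is.finite(X))) stop("non-finite spatial features")
  pn_all <- model$params
  if (ncol(X) != nrow(pn_all[["spb.W1"]])) stop("feature width mismatch")
  tape <- ad_tape()
  pn <- const_pnodes(tape, pn_all)
  r_s <- spb_graph(tape, pick(pn, "spb"), ad_const(tape, X))
  r_s$value
}

# ---- morphological branch (MpB) attention tower ----

mpb_init <- function(d_m = 64L, h = 32L, a = 16L, seed = 1L) {
  att <- attention_params(d_m, h, a, seed + 2L)
  params <- stats::setNames(att, paste0("mpb.", names(att)))
  structure(list(type = "mpb", params = params,
                 config = list(d_m = d_m, h = h, a = a, seed = seed)),
            class = "tls_net")
}

# ---- MVNet fusion ----

#' MVNet: two-branch multi-view fusion
#'
#' `mvnet_init` assembles the full multi-view model: the SpB MLP, the MpB
#' attention tower over the 7 morphological cluster centers, and the fusion
#' module. `mvnet_fuse` implements the fusion equation on given branch
#' representations:
#' \deqn{f_{fusion} = \mathrm{concat}\big(W_{fusion}(f_S \odot f_{mvS}),\;
#'   W_{fusion}(f_M \odot f_{mvM})\big)}
#' where f_S and f_M are linear maps of r_S and r_M, and f_mvS, f_mvM are
#' two linear maps of the concatenated multi-view vector
#' r_mv = concat(r_S, r_M). The shared matrix W_fusion maps width 32 to 16,
#' so f_fusion (width 32) is the penultimate representation fed to the
#' two-class linear head (and, in MMF, concatenated with the clinical
#' embedding).
#'
#' @param d_in spatial feature width (226).
#' @param d_m morphological embedding width (default 64).
#' @param seed RNG seed.
#' @param spb,mpb optional pretrained branch models whose parameters
#'   warm-start the corresponding towers.
#' @return `mvnet_init`: model list; `mvnet_fuse`: list with `f_fusion`,
#'   `prob`, `penultimate`.
#' @export
mvnet_init <- function(d_in = 226L, d_m = 64L, seed = 1L,
                       spb = NULL, mpb = NULL) {
  spb_par <- if (is.null(spb)) spb_init(d_in, seed = seed)$params
             else spb$params[startsWith(names(spb$params), "spb.")]
  mpb_par <- if (is.null(mpb)) mpb_init(d_m, seed = seed)$params
             else mpb$params[startsWith(names(mpb$params), "mpb.")]
  fus <- with_seed(seed + 3L, list(
    Ws = init_mat(32L, 32L), bs = init_bias(32L),
    Wm = init_mat(32L, 32L), bm = init_bias(32L),
    Wmvs = init_mat(64L, 32L), bmvs = init_bias(32L),
    Wmvm = init_mat(64L, 32L), bmvm = init_bias(32L),
    Wfusion = init_mat(32L, 16L),
    Wc = init_mat(32L, 2L), bc = init_bias(2L)
  ))
  params <- c(spb_par, mpb_par,
              stats::setNames(fus, paste0("fus.", names(fus))))
  structure(list(type = "mvnet", params = params,
                 config = list(d_in = d_in, d_m = d_m, seed = seed)),
            class = "tls_net")
}

fusion_graph <- function(tape, pn, r_s, r_m) {
  r_mv <- ad_cbind(tape, r_s, r_m)
  f_s <- ad_linear(tape, r_s, pn$Ws, pn$bs)
  f_m <- ad_linear(tape, r_m, pn$Wm, pn$bm)
  f_mvs <- ad_linear(tape, r_mv, pn$Wmvs, pn$bmvs)
  f_mvm <- ad_linear(tape, r_mv, pn$Wmvm, pn$bmvm)
  left <- ad_matmul(tape, ad_mul(tape, f_s, f_mvs), pn$Wfusion)
  right <- ad_matmul(tape, ad_mul(tape, f_m, f_mvm), pn$Wfusion)
  pen <- ad_cbind(tape, left, right)
  logits <- ad_linear(tape, pen, pn$Wc, pn$bc)
  list(pen = pen, logits = logits)
}

#' @rdname mvnet_init
#' @param r_s spatial representation(s): length-32 vector or n x 32 matrix.
#' @param r_m morphological representation(s), same row count.
#' @param model an `mvnet_init` model.
#' @export
mvnet_fuse <- function(r_s, r_m, model) {
  Rs <- if (is.matrix(r_s)) r_s else matrix(r_s, nrow = 1L)
  Rm <- if (is.matrix(r_m)) r_m else matrix(r_m, nrow = 1L)
  if (ncol(Rs) != 32L || ncol(Rm) != 32L || nrow(Rs) != nrow(Rm))
    stop("branch representations must be 32-wide with matching rows")
  tape <- ad_tape()
  pn <- pick(const_pnodes(tape, model$params), "fus")
  g <- fusion_graph(tape, pn, ad_const(tape, Rs), ad_const(tape, Rm))
  list(f_fusion = g$pen$value,
       penultimate = g$pen$value,
       prob = ad_softmax_rows(g$logits$value))
}

# ---- multi-modal fusion (MMF) ----

#' MMF: clinical multi-modal fusion
#'
#' A four-layer clinical tower (14 -> 64 -> 64 -> 64 -> 32; each layer
#' affine + batch normalization + ReLU) embeds the 14 clinicopathological
#' covariates; the 32-dimensional clinical embedding is concatenated with
#' the 32-dimensional MVNet penultimate representation into a 64-dimensional
#' fused vector classified by a final linear layer. The whole stack is
#' optimized end-to-end with the final prediction loss.
#'
#' @param mvnet a (typically trained) `mvnet_init` model to embed.
#' @param d_c clinical width (14).
#' @param seed RNG seed.
#' @return `mmf_init`: model list; `mmf_forward`: list with `prob`,
#'   `fused` (64-wide), `clinical_embedding` (32-wide).
#' @export
mmf_init <- function(mvnet, d_c = 14L, seed = 1L) {
  dims <- c(d_c, 64L, 64L, 64L, 32L)
  clin <- with_seed(seed + 4L, {
    out <- list()
    for (i in 1:4) {
      out[[paste0("W", i)]] <- init_mat(dims[i], dims[i + 1L])
      out[[paste0("b", i)]] <- init_bias(dims[i + 1L])
      out[[paste0("g", i)]] <- rep(1, dims[i + 1L])
      out[[paste0("beta", i)]] <- numeric(dims[i + 1L])
    }
    out$Wout <- init_mat(64L, 2L)
    out$bout <- init_bias(2L)
    out
  })
  params <- c(mvnet$params, stats::setNames(clin, paste0("clin.", names(clin))))
  bn <- lapply(1:4, function(i) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- numeric(dims[i + 1L])
    e$running_var <- rep(1, dims[i + 1L])
    e
  })
  structure(list(type = "mmf", params = params, bn = bn,
                 config = c(mvnet$config, list(d_c = d_c, seed = seed))),
            class = "tls_net")
}

clin_graph <- function(tape, pn, Cnode, bn, training) {
  x <- Cnode
  for (i in 1:4) {
    x <- ad_linear(tape, x, pn[[paste0("W", i)]], pn[[paste0("b", i)]])
    x <- ad_batchnorm(tape, x, pn[[paste0("g", i)]], pn[[paste0("beta", i)]],
                      bn[[i]], training)
    x <- ad_relu(tape, x)
  }
  x
}

#' @rdname mmf_init
#' @param clinical length-14 numeric vector or n x 14 matrix of encoded
#'   covariates.
#' @param mvnet_penultimate matching 32-wide MVNet penultimate rows.
#' @param model an `mmf_init` model (evaluation mode: frozen batch-norm
#'   statistics, so repeated calls are bit-identical).
#' @export
mmf_forward <- function(clinical, mvnet_penultimate, model) {
  C <- if (is.matrix(clinical)) clinical else matrix(clinical, nrow = 1L)
  P <- if (is.matrix(mvnet_penultimate)) mvnet_penultimate
       else matrix(mvnet_penultimate, nrow = 1L)
  if (ncol(C) != model$config$d_c)
    stop(sprintf("clinical vector must have width %d", model$config$d_c))
  if (ncol(P) != 32L || nrow(P) != nrow(C))
    stop("penultimate rows must be 32-wide and match clinical rows")
  tape <- ad_tape()
  pn <- pick(const_pnodes(tape, model$params), "clin")
  emb <- clin_graph(tape, pn, ad_const(tape, C), model$bn, training = FALSE)
  fused <- cbind(emb$value, P)
  logits <- fused %*% model$params[["clin.Wout"]]
  logits <- sweep(logits, 2L, model$params[["clin.bout"]], "+")
  list(prob = ad_softmax_rows(logits),
       fused = fused,
       clinical_embedding = emb$value)
}

# ---- full-model graph used by training and batch prediction ----
#
# data: list with any of
#   spatial: n x 226 standardized matrix
#   centers: (7n) x d_m stacked morph cluster centers, center_groups: 1..n
#   clinical: n x 14 standardized matrix
#   bags: (sum N_i) x d_p stacked patch features, bag_groups: 1..n
net_graph <- function(tape, model, pn, data, training = FALSE) {
  type <- model$type
  if (type == "wsinet") {
    g <- ga_graph(tape, pick(pn, "att"), ad_const(tape, data$bags),
                  data$bag_groups)
    logits <- ad_linear(tape, g$pooled, pn$head.W, pn$head.b)
    return(list(logits = logits, attention = g$S))
  }
  if (type == "spb") {
    r_s <- spb_graph(tape, pick(pn, "spb"), ad_const(tape, data$spatial))
    logits <- ad_linear(tape, r_s, pn$head.W, pn$head.b)
    return(list(logits = logits, r_s = r_s))
  }
  if (type == "mpb") {
    g <- ga_graph(tape, pick(pn, "mpb"), ad_const(tape, data$centers),
                  data$center_groups)
    logits <- ad_linear(tape, g$pooled, pn$head.W, pn$head.b)
    return(list(logits = logits, r_m = g$pooled))
  }
  if (type %in% c("mvnet", "mmf")) {
    r_s <- spb_graph(tape, pick(pn, "spb"), ad_const(tape, data$spatial))
    g <- ga_graph(tape, pick(pn, "mpb"), ad_const(tape, data$centers),
                  data$center_groups)
    fg <- fusion_graph(tape, pick(pn, "fus"), r_s, g$pooled)
    if (type == "mvnet")
      return(list(logits = fg$logits, penultimate = fg$pen))
    emb <- clin_graph(tape, pick(pn, "clin"), ad_const(tape, data$clinical),
                      model$bn, training)
    fused <- ad_cbind(tape, emb, fg$pen)
    logits <- ad_linear(tape, fused, pn$clin.Wout, pn$clin.bout)
    return(list(logits = logits, fused = fused))
  }
  stop(sprintf("unknown model type '%s'", type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-branch classifier variants carry their own linear head
add_head <- function(model, width, seed = 1L) {
  head <- with_seed(seed + 9L, list(W = init_mat(width, 2L),
                                    b = init_bias(2L)))
  model$params <- c(model$params,
                    stats::setNames(head, paste0("head.", names(head))))
  model
}
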