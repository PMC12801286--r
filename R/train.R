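# Training protocol: class-weighted loss, stratified 5-fold case-level CV,
# ensemble averaging, Equal-Error-Rate thresholding.

#' Assemble a cohort object
#'
#' The container consumed by the training protocol. All components are
#' case-aligned.
#'
#' @param cases data frame with columns `case_id`, `relapse_label` (0/1),
#'   `rfs_time_months` (> 0), `event` (0/1), `act_flag` (0/1).
#' @param spatial n x 226 matrix of spatial feature vectors.
#' @param morph list of n `morph_bag` objects.
#' @param clinical optional n x 14 matrix of encoded covariates.
#' @param bags optional list of n patch-feature matrices (N_i x d_p).
#' @param truth optional generator ground-truth table (synthetic cohorts).
#' @return A `tls_cohort` list.
#' @export
tls_cohort <- function(cases, spatial = NULL, morph = NULL, clinical = NULL,
                       bags = NULL, truth = NULL) {
  req <- c("case_id", "relapse_label", "rfs_time_months", "event", "act_flag")
  missing_cols <- setdiff(req, names(cases))
  if (length(missing_cols))
    stop("cases table lacks columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(all(cases$relapse_label %in% c(0, 1)),
            all(cases$rfs_time_months > 0), all(cases$event %in% c(0, 1)))
  n <- nrow(cases)
  for (nm in c("spatial", "clinical")) {
    m <- get(nm)
    if (!is.null(m) && nrow(m) != n)
      stop(sprintf("'%s' must have one row per case", nm))
  }
  if (!is.null(morph) && length(morph) != n)
    stop("'morph' must have one bag per case")
  if (!is.null(bags) && length(bags) != n)
    stop("'bags' must have one matrix per case")
  structure(list(cases = cases, spatial = spatial, morph = morph,
                 clinical = clinical, bags = bags, truth = truth),
            class = "tls_cohort")
}

#' @export
print.tls_cohort <- function(x, ...) {
  cat(sprintf("tls_cohort: %d cases (%d relapse, %d events)\n",
              nrow(x$cases), sum(x$cases$relapse_label),
              sum(x$cases$event)))
  parts <- c(spatial = !is.null(x$spatial), morph = !is.null(x$morph),
             clinical = !is.null(x$clinical), bags = !is.null(x$bags))
  cat("components:", paste(names(parts)[parts], collapse = ", "), "\n")
  invisible(x)
}

#' Model/training specification
#'
#' Collects the protocol constants for one model variant. Defaults follow
#' the training protocol: Adam at 1e-3, class weights 0.5 (no relapse) and
#' 1.2 (relapse), full-batch training, 500 epochs for prognostic models,
#' inverse-time learning-rate decay (rate 9e-3) for the multi-view models
#' and cosine decay with 10-epoch linear warm-up for WSINet and MMF.
#'
#' @param type one of `"spb"`, `"mpb"`, `"mvnet"`, `"mmf"`, `"wsinet"`.
#' @param epochs training epochs (default 500).
#' @param pretrain_epochs branch pretraining epochs for MVNet/MMF
#'   (default 200).
#' @param lr initial learning rate.
#' @param schedule `"inverse_time"`, `"warmup_cosine"` or `"constant"`.
#' @param decay_rate inverse-time decay rate (default 9e-3).
#' @param warmup warm-up epochs for the cosine schedule.
#' @param w0,w1 class weights.
#' @param weight_decay decoupled weight decay applied by Adam
#'   (default 1e-2; full-batch training over hundreds of epochs on cohort-
#'   sized data needs explicit capacity control).
#' @param d_m morphological embedding width.
#' @param d_p patch feature width (WSINet).
#' @return A `model_spec` list.
#' @export
model_spec <- function(type = c("mvnet", "spb", "mpb", "mmf", "wsinet"),
                       epochs = 500L, pretrain_epochs = 200L, lr = 1e-3,
                       schedule = NULL, decay_rate = 9e-3, warmup = 10L,
                       w0 = 0.5, w1 = 1.2, weight_decay = NULL,
                       d_m = 64L, d_p = 768L) {
  type <- match.arg(type)
  if (is.null(schedule))
    schedule <- if (type %in% c("wsinet", "mmf")) "warmup_cosine"
                else "inverse_time"
  if (is.null(weight_decay)) weight_decay <- 1e-2
  structure(list(type = type, epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs), lr = lr,
                 schedule = schedule, decay_rate = decay_rate,
                 warmup = as.integer(warmup), w0 = w0, w1 = w1,
                 weight_decay = weight_decay, d_m = as.integer(d_m),
                 d_p = as.integer(d_p)),
            class = "model_spec")
}

lr_schedule_fn <- function(spec, epochs) {
  switch(spec$schedule,
         inverse_time = lr_inverse_time(spec$lr, spec$decay_rate),
         warmup_cosine = lr_warmup_cosine(spec$lr, spec$warmup, epochs),
         constant = function(epoch) spec$lr,
         stop("unknown schedule"))
}

#' Stratified case-level fold assignment
#'
#' Partitions cases into `k` folds, stratified by label so every fold sees
#' both classes; errors when a class has fewer members than folds.
#'
#' @param labels case labels in \{0, 1\}.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the same seed reproduces the same split.
#' @return Integer fold assignment (1..k) per case.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (any(table(labels) < k))
    stop("a class has fewer members than folds; cannot stratify")
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# per-column standardization fitted on training rows only (no leakage)
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$mu), 2L, std$sd, "/")
}

# builds the net_graph data list for the given case indices
build_net_data <- function(cohort, spec, idx, std) {
  out <- list()
  if (spec$type %in% c("spb", "mvnet", "mmf")) {
    out$spatial <- apply_standardizer(
      cohort$spatial[idx, , drop = FALSE], std$spatial)
  }
  if (spec$type %in% c("mpb", "mvnet", "mmf")) {
    out$centers <- do.call(rbind, lapply(cohort$morph[idx],
                                         function(b) b$centers))
    k <- nrow(cohort$morph[[1]]$centers)
    out$center_groups <- rep(seq_along(idx), each = k)
  }
  if (spec$type == "mmf") {
    out$clinical <- apply_standardizer(
      cohort$clinical[idx, , drop = FALSE], std$clinical)
  }
  if (spec$type == "wsinet") {
    out$bags <- do.call(rbind, cohort$bags[idx])
    out$bag_groups <- rep(seq_along(idx),
                          vapply(cohort$bags[idx], nrow, 0L))
  }
  out
}

init_net <- function(spec, cohort, seed, spb = NULL, mpb = NULL,
                     mvnet = NULL) {
  switch(spec$type,
    spb = add_head(spb_init(ncol(cohort$spatial), seed = seed), 32L, seed),
    mpb = add_head(mpb_init(spec$d_m, seed = seed), 32L, seed),
    mvnet = mvnet_init(ncol(cohort$spatial), spec$d_m, seed = seed,
                       spb = spb, mpb = mpb),
    mmf = mmf_init(mvnet, seed = seed),
    wsinet = wsinet_init(ncol(cohort$bags[[1]]), seed = seed))
}

# full-batch Adam loop; returns the trained model plus loss and lr traces
train_loop <- function(model, data, y, spec, epochs = spec$epochs) {
  schedule <- lr_schedule_fn(spec, epochs)
  opt <- adam_state(model$params)
  loss_trace <- lr_trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    tape <- ad_tape()
    pn <- make_pnodes(tape, model$params)
    out <- net_graph(tape, model, pn, data, training = TRUE)
    loss <- ad_wce_loss(tape, out$logits, y, spec$w0, spec$w1)
    ad_backward(tape, loss)
    grads <- ad_param_grads(tape)
    lr <- schedule(epoch)
    step <- adam_step(model$params, grads, opt, lr,
                      weight_decay = spec$weight_decay)
    model$params <- step$params
    opt <- step$state
    loss_trace[epoch] <- loss$value
    lr_trace[epoch] <- lr
  }
  model$loss_trace <- loss_trace
  model$lr_trace <- lr_trace
  model
}

# trains one model (with branch pretraining where the type requires it) on
# the given training cases; all standardization statistics come from those
# cases only
train_one <- function(cohort, spec, idx_train, seed) {
  std <- list()
  if (!is.null(cohort$spatial))
    std$spatial <- fit_standardizer(cohort$spatial[idx_train, , drop = FALSE])
  if (!is.null(cohort$clinical))
    std$clinical <- fit_standardizer(cohort$clinical[idx_train, , drop = FALSE])
  y <- cohort$cases$relapse_label[idx_train]

  pretrain_branch <- function(btype) {
    bspec <- spec
    bspec$type <- btype
    m <- init_net(bspec, cohort, seed)
    train_loop(m, build_net_data(cohort, bspec, idx_train, std), y, bspec,
               epochs = spec$pretrain_epochs)
  }

  model <-
    if (spec$type %in% c("mvnet", "mmf")) {
      spb <- pretrain_branch("spb")
      mpb <- pretrain_branch("mpb")
      mv_spec <- spec; mv_spec$type <- "mvnet"
      mv <- init_net(mv_spec, cohort, seed, spb = spb, mpb = mpb)
      mv <- train_loop(mv, build_net_data(cohort, mv_spec, idx_train, std),
                       y, mv_spec)
      if (spec$type == "mvnet") mv
      else {
        m <- init_net(spec, cohort, seed, mvnet = mv)
        train_loop(m, build_net_data(cohort, spec, idx_train, std), y, spec)
      }
    } else {
      m <- init_net(spec, cohort, seed)
      train_loop(m, build_net_data(cohort, spec, idx_train, std), y, spec)
    }
  list(model = model, std = std, spec = spec)
}

# evaluation-mode class-1 probabilities for the given cases
predict_one <- function(trained, cohort, idx = seq_len(nrow(cohort$cases))) {
  data <- build_net_data(cohort, trained$spec, idx, trained$std)
  tape <- ad_tape()
  pn <- const_pnodes(tape, trained$model$params)
  out <- net_graph(tape, trained$model, pn, data, training = FALSE)
  ad_softmax_rows(out$logits$value)[, 2L]
}

#' Cross-validated training
#'
#' Stratified 5-fold case-level cross-validation: each fold serves as the
#' held-out set once, predicted by the model trained exclusively on the
#' remaining folds; the concatenated out-of-fold predictions form the
#' complete internal test set. Feature standardization is fitted per fold
#' on the training cases only.
#'
#' @param cohort a `tls_cohort`.
#' @param spec a [model_spec()].
#' @param seed RNG seed controlling the fold split and all initializations.
#' @param k number of folds (default 5).
#' @return A `tls_cv` list: `predictions` (case_id, probability, fold),
#'   `models` (k trained fold models), `folds`, `spec`, `seed`.
#' @export
run_cv <- function(cohort, spec, seed = 1L, k = 5L) {
  stopifnot(inherits(cohort, "tls_cohort"), inherits(spec, "model_spec"))
  labels <- cohort$cases$relapse_label
  if (nrow(cohort$cases) < 10L) stop("need at least 10 cases")
  folds <- make_folds(labels, k, seed)
  probs <- rep(NA_real_, length(labels))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    idx_test <- which(folds == f)
    idx_train <- which(folds != f)
    trained <- train_one(cohort, spec, idx_train, seed = seed * 1000L + f)
    probs[idx_test] <- predict_one(trained, cohort, idx_test)
    models[[f]] <- trained
  }
  structure(list(
    predictions = data.frame(case_id = cohort$cases$case_id,
                             probability = probs, fold = folds,
                             stringsAsFactors = FALSE),
    models = models, folds = folds, spec = spec, seed = seed),
    class = "tls_cv")
}

#' Ensemble prediction from cross-validated models
#'
#' Arithmetic mean of the per-model probabilities; used when applying the
#' development-cohort models to an external cohort (only the ensemble mean
#' is later binarized).
#'
#' @param models list of trained fold models (from [run_cv()]).
#' @param cohort a `tls_cohort` to predict.
#' @return Numeric vector of ensemble probabilities.
#' @export
ensemble_predict <- function(models, cohort) {
  if (!length(models) || any(vapply(models, is.null, TRUE)))
    stop("all fold models are required for the ensemble")
  P <- vapply(models, predict_one, numeric(nrow(cohort$cases)),
              cohort = cohort)
  rowMeans(P)
}
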