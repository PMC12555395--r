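#' Enumerate the architectural design space
#'
#' One row per variant of the sweeps the design space exposes: GCASM depth
#' 1-4, local graph size k in {10, 20, 30, 40}, the five neighborhood
#' metrics (squared Euclidean; Pearson; cosine; 0.5/0.5 and 0.7/0.3
#' distance-cosine combinations), the attention variants, the alignment
#' network on/off, and the Gaussian noise levels sigma in
#' {0, 0.01, 0.02, 0.04, 0.08}.
#'
#' @return data.frame with columns `sweep`, `name`, and the varied setting
#'   columns (`n_layers`, `k`, `metric`, `weight`, `attn`, `transnet`,
#'   `sigma`), `NA` where a column is not varied.
#' @export
ablation_variants <- function() {
  base <- data.frame(sweep = character(), name = character(),
                     n_layers = integer(), k = integer(),
                     metric = character(), weight = numeric(),
                     attn = character(), transnet = logical(),
                     sigma = numeric(), stringsAsFactors = FALSE)
  row <- function(sweep, name, n_layers = NA_integer_, k = NA_integer_,
                  metric = NA_character_, weight = NA_real_,
                  attn = NA_character_, transnet = NA, sigma = NA_real_) {
    data.frame(sweep = sweep, name = name, n_layers = n_layers, k = k,
               metric = metric, weight = weight, attn = attn,
               transnet = transnet, sigma = sigma,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (L in 1:4)
    rows <- c(rows, list(row("layers", paste0(L, "_layers"), n_layers = L)))
  for (k in c(10L, 20L, 30L, 40L))
    rows <- c(rows, list(row("k", paste0("k", k), k = k)))
  metrics <- list(
    list("A_sq_euclidean", "sq_euclidean", NA_real_),
    list("B_pearson", "pearson", NA_real_),
    list("C_cosine", "cosine", NA_real_),
    list("D_weighted_0.5", "weighted", 0.5),
    list("E_weighted_0.7", "weighted", 0.7))
  for (m in metrics)
    rows <- c(rows, list(row("metric", m[[1]], metric = m[[2]],
                             weight = m[[3]])))
  for (a in c("gcasm", "general", "multihead4", "multihead8"))
    rows <- c(rows, list(row("attention", a, attn = a)))
  for (tn in c(TRUE, FALSE))
    rows <- c(rows, list(row("transnet",
                             if (tn) "with_transnet" else "no_transnet",
                             transnet = tn)))
  for (s in c(0, 0.01, 0.02, 0.04, 0.08))
    rows <- c(rows, list(row("noise", paste0("sigma", s), sigma = s)))
  do.call(rbind, c(list(base), rows))
}

variant_config <- function(v, base_cfg) {
  args <- list(n_classes = base_cfg$n_classes,
               n_gcasm_layers = base_cfg$n_gcasm_layers,
               channels = base_cfg$channels, k = base_cfg$k,
               global_dim = base_cfg$global_dim,
               head_dims = base_cfg$head_dims,
               dropout_rate = base_cfg$dropout_rate,
               attn_variant = base_cfg$attn_variant,
               graph_metric = base_cfg$graph_metric,
               weight_sq_euclid = base_cfg$weight_sq_euclid,
               graph_space = base_cfg$graph_space,
               use_transnet = base_cfg$use_transnet)
  if (!is.na(v$n_layers)) {
    args$n_gcasm_layers <- v$n_layers
    args$channels <- rep(base_cfg$channels[1L], v$n_layers)
  }
  if (!is.na(v$k)) args$k <- v$k
  if (!is.na(v$metric)) args$graph_metric <- v$metric
  if (!is.na(v$weight)) args$weight_sq_euclid <- v$weight
  if (!is.na(v$attn)) args$attn_variant <- v$attn
  if (!is.na(v$transnet)) args$use_transnet <- v$transnet
  do.call(model_config, args)
}

#' Run the full ablation harness
#'
#' For every design-space variant: build the configuration, initialize
#' parameters, run one SGD forward/backward step on a batch of clouds
#' (after the variant's noise perturbation where applicable), verify every
#' parameter group received gradient, and evaluate the (untrained) model on
#' the same clouds. This is a structural harness — it certifies that the
#' whole design space constructs, trains and evaluates — not a performance
#' benchmark.
#'
#' @param clouds List of labeled clouds (all `N >= 41` so `k = 40`
#'   variants run).
#' @param base_cfg Baseline [model_config()] the variants perturb
#'   (defaults to [reduced_model_config()] with the cloud's class count).
#' @param lr Learning rate of the single step.
#' @param seed Seed for init and perturbations.
#' @return data.frame: one row per variant with `loss` (finite),
#'   `grad_ok` (all parameter groups have nonzero gradient norm), `acc`
#'   and `miou` after the step.
#' @export
run_ablation <- function(clouds, base_cfg = NULL, lr = 0.01, seed = 1L) {
  P <- max(vapply(clouds, function(cl) max(cl$labels), numeric(1))) + 1L
  if (is.null(base_cfg)) base_cfg <- reduced_model_config(n_classes = P)
  vs <- ablation_variants()
  out <- vector("list", nrow(vs))
  for (r in seq_len(nrow(vs))) {
    v <- vs[r, ]
    cfg <- variant_config(v, base_cfg)
    batch <- clouds
    if (!is.na(v$sigma) && v$sigma > 0)
      batch <- lapply(seq_along(clouds), function(i)
        gaussian_perturb(clouds[[i]], v$sigma, seed = seed + i))
    params <- gcassn_init(cfg, seed = seed)
    res <- with_seed(seed + r, {
      grads <- NULL
      loss <- 0
      for (cl in batch) {
        fw <- gcassn_fwd_full(cl$coords, params, cfg, train = TRUE)
        ce <- cross_entropy(fw$logits, cl$labels)
        loss <- loss + ce$loss
        grads <- grad_add(grads,
                          gcassn_bwd_full(ce$dlogits, fw$cache, params,
                                          cfg, train = TRUE))
      }
      grads <- grad_scale(grads, 1 / length(batch))
      grad_ok <- all(vapply(grads, grad_norm, numeric(1)) > 0)
      params <- sgd_step(params, grads, NULL, lr, 0.9, 1e-4)$p
      m <- evaluate(params, cfg, batch)
      list(loss = loss / length(batch), grad_ok = grad_ok,
           acc = m$acc_overall, miou = m$miou)
    })
    out[[r]] <- data.frame(sweep = v$sweep, name = v$name,
                           loss = res$loss, grad_ok = res$grad_ok,
                           acc = res$acc, miou = res$miou,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
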