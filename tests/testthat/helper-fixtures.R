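# Shared fixtures, built once per test run.

fixture_env <- new.env()

# a small deterministic phantom at tiny scale
tiny_phantom <- function(seed = 42, ...) {
  key <- paste0("ph_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_phantom(phantom_spec(seed = seed, ...),
                                           grid_profile("tiny"))
  fixture_env[[key]]
}

# preprocessed (shape + voxel normalized, centred) tiny phantom
tiny_normalized <- function(seed = 42, ...) {
  key <- paste0("nv_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(fixture_env[[key]])) {
    v <- normalize_shape(tiny_phantom(seed, ...), profile = grid_profile("tiny"))
    fixture_env[[key]] <- center_volume(normalize_voxels(v))
  }
  fixture_env[[key]]
}

# a micro network: full architecture family at reduced width/depth
micro_net <- function(dims = c(7, 8, 9), seed = 3) {
  cfg <- model_config(init_filters = 4L, layers_per_block = 2L,
                      dense_blocks = 2L, growth = 6L,
                      fc_widths = c(256L, 128L), dropout = 0)
  build_model(cfg, dims, seed = seed)
}

# a hand-built linear "network": flatten + a single linear regression head.
# Used as the analytic oracle for gradients x input.
linear_net <- function(dims, weights) {
  par <- new.env(parent = emptyenv())
  par[["hW"]] <- matrix(weights, ncol = 1)
  par[["hb"]] <- 0
  nfeat <- prod(dims)
  structure(list(
    cfg = model_config(class_heads = character(0), reg_heads = "y",
                       fc_widths = c(256L, 128L)),
    input_dims = as.integer(dims),
    nodes = list(list(type = "flatten", sp = as.integer(dims), c = 1L,
                      nfeat = nfeat)),
    heads = list(y = list(kind = "reg", W = "hW", b = "hb")),
    par = par, param_keys = character(0), state_keys = character(0),
    embedding_dim = nfeat, final_sp = as.integer(dims), final_ch = 1L),
    class = "adiponet_net")
}

# brute-force AUROC over all positive-negative pairs (ties count 1/2)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive k-medoids: minimal total distance to closest medoid
exhaustive_medoid_cost <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  costs <- apply(combos, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min)))
  min(costs)
}

pam_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}
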