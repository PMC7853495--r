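# Declarative model specification, exact parameter accounting, and
# construction of the semi-Siamese U-Net and the classical U-Net baseline.

#' Specify a separation network
#'
#' The architecture family is a five-block contracting path (two 3x3
#' convolutions per block, 2x2 max-pooling after blocks 1-4, dropout after
#' the convolutions of blocks 4 and 5) and one or two expanding paths.  Each
#' expanding-path block is 2x nearest-neighbour upsampling, a 2x2
#' convolution, channel concatenation with the symmetric contracting block,
#' and two 3x3 convolutions; the head is a 3x3 convolution to 2 channels
#' followed by a 1x1 convolution to 1 sigmoid channel.  All convolutions are
#' biased and same-padded; there are no normalization layers.  At full scale
#' (`base_filters = 64`) the encoder filter progression is
#' 64-128-256-512-1024.
#'
#' @param input_size Square input side, divisible by 16 (256 at full scale,
#'   64 for reduced runs).
#' @param base_filters Filters of the first block (64 at full scale).
#' @param width_scale Convenience scaling of `base_filters` (e.g. `1/4` for
#'   the reduced 16-filter model); applied multiplicatively.
#' @param dropout_rate Dropout rate after encoder blocks 4 and 5
#'   (default 0.5).
#' @return A list of class `separation_model_spec`.
#' @examples
#' spec <- separation_model_spec()            # full scale
#' spec_small <- separation_model_spec(64, width_scale = 1/4)
#' @export
separation_model_spec <- function(input_size = 256L, base_filters = 64L,
                                  width_scale = 1, dropout_rate = 0.5) {
  bf <- as.integer(round(base_filters * width_scale))
  if (input_size %% 16 != 0) {
    stop("input_size must be divisible by 16 (four 2x2 poolings)")
  }
  stopifnot(bf >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_size = as.integer(input_size), input_channels = 1L,
                 base_filters = bf, depth = 5L,
                 dropout_rate = dropout_rate),
            class = "separation_model_spec")
}

# one decoder's ledger rows (path label supplied by caller)
decoder_ledger_rows <- function(f, path) {
  rows <- list()
  blocks <- c(6, 7, 8, 9)
  for (i in seq_along(blocks)) {
    l <- 5 - i                      # encoder level being restored (4..1)
    fi <- f[l]; fprev <- f[l + 1]
    blk <- paste0("block", blocks[i])
    rows[[length(rows) + 1]] <- list(path, blk, "up_conv2x2", 2L, 2L,
                                     fprev, fi)
    rows[[length(rows) + 1]] <- list(path, blk, "conv3x3_a", 3L, 3L,
                                     2L * fi, fi)
    rows[[length(rows) + 1]] <- list(path, blk, "conv3x3_b", 3L, 3L, fi, fi)
  }
  rows[[length(rows) + 1]] <- list(path, "head", "conv3x3_out", 3L, 3L,
                                   f[1], 2L)
  rows[[length(rows) + 1]] <- list(path, "head", "conv1x1_out", 1L, 1L,
                                   2L, 1L)
  rows
}

#' Exact per-layer parameter ledger
#'
#' Closed-form accounting of every convolution: parameters per layer are
#' `kh * kw * c_in * c_out + c_out` (bias included, no normalization
#' layers).  The ledger total equals the built network's trainable-parameter
#' count exactly.
#'
#' @param spec A [separation_model_spec()].
#' @param architecture `"semi_siamese"` (shared encoder, two decoders) or
#'   `"classical"` (one encoder, one decoder).
#' @return A tibble with columns `path`, `block`, `layer`, `kh`, `kw`,
#'   `c_in`, `c_out`, `params`.
#' @examples
#' sum(layer_ledger(separation_model_spec())$params)  # 43221322
#' @export
layer_ledger <- function(spec, architecture = c("semi_siamese",
                                                "classical")) {
  architecture <- match.arg(architecture)
  f <- spec$base_filters * 2^(0:4)
  rows <- list()
  for (b in 1:5) {
    cin <- if (b == 1) spec$input_channels else f[b - 1]
    rows[[length(rows) + 1]] <- list("encoder", paste0("block", b),
                                     "conv3x3_a", 3L, 3L, cin, f[b])
    rows[[length(rows) + 1]] <- list("encoder", paste0("block", b),
                                     "conv3x3_b", 3L, 3L, f[b], f[b])
  }
  ndec <- if (architecture == "semi_siamese") 2L else 1L
  for (j in seq_len(ndec)) {
    rows <- c(rows, decoder_ledger_rows(f, paste0("decoder", j)))
  }
  out <- tibble::tibble(
    path = vapply(rows, `[[`, "", 1),
    block = vapply(rows, `[[`, "", 2),
    layer = vapply(rows, `[[`, "", 3),
    kh = vapply(rows, function(r) as.integer(r[[4]]), 1L),
    kw = vapply(rows, function(r) as.integer(r[[5]]), 1L),
    c_in = vapply(rows, function(r) as.integer(r[[6]]), 1L),
    c_out = vapply(rows, function(r) as.integer(r[[7]]), 1L))
  out$params <- as.numeric(out$kh) * out$kw * out$c_in * out$c_out + out$c_out
  out
}

#' Build the semi-Siamese U-Net (shared encoder, two parallel decoders)
#'
#' The two decoders have identical topology and branch from the fifth
#' encoder block; the encoder weights are shared by construction (a single
#' instance feeds both decoders).  Decoder 1 is the lung path, decoder 2 the
#' heart path.
#'
#' @param spec A [separation_model_spec()].
#' @param seed Weight-initialization seed (Glorot-uniform).
#' @return An object of class `eitsep_model` wrapping the native network,
#'   its spec and its layer ledger.
#' @examples
#' m <- build_semi_siamese(separation_model_spec(64, width_scale = 1/4))
#' count_parameters(m)
#' @export
build_semi_siamese <- function(spec, seed = 1L) {
  ptr <- cpp_unet_create(spec$input_size, spec$base_filters, 2L,
                         spec$dropout_rate, as.integer(seed))
  new_model(ptr, spec, "semi_siamese", seed,
            layer_ledger(spec, "semi_siamese"))
}

#' Build a classical single-decoder U-Net
#'
#' One encoder and one decoder of the same layer topology as the
#' semi-Siamese network.  The separation baseline is a *dual* U-Net: two
#' independent such networks, one per organ (see [build_dual_unet()]).
#'
#' @inheritParams build_semi_siamese
#' @return An `eitsep_model` with a single decoder.
#' @export
build_classical_unet <- function(spec, seed = 1L) {
  ptr <- cpp_unet_create(spec$input_size, spec$base_filters, 1L,
                         spec$dropout_rate, as.integer(seed))
  new_model(ptr, spec, "classical", seed, layer_ledger(spec, "classical"))
}

#' Build the dual U-Net baseline (two independent classical U-Nets)
#'
#' @inheritParams build_semi_siamese
#' @return An object of class `eitsep_dual`: independent lung and heart
#'   networks.
#' @export
build_dual_unet <- function(spec, seed = 1L) {
  structure(list(
    lung = build_classical_unet(spec, seed),
    heart = build_classical_unet(spec, seed + 1L),
    spec = spec, architecture = "dual_unet", seed = seed),
    class = "eitsep_dual")
}

new_model <- function(ptr, spec, architecture, seed, ledger) {
  eng <- cpp_unet_layers(ptr)
  if (sum(eng$params) != sum(ledger$params)) {
    stop("internal error: engine parameter count disagrees with the ledger")
  }
  structure(list(ptr = ptr, spec = spec, architecture = architecture,
                 seed = seed, ledger = ledger),
            class = "eitsep_model")
}

#' Count trainable parameters
#'
#' @param model An `eitsep_model` or `eitsep_dual`.
#' @return Exact trainable-parameter count (convolution weights + biases).
#' @examples
#' count_parameters(build_semi_siamese(separation_model_spec(64, 16)))
#' @export
count_parameters <- function(model) {
  if (inherits(model, "eitsep_dual")) {
    return(count_parameters(model$lung) + count_parameters(model$heart))
  }
  stopifnot(inherits(model, "eitsep_model"))
  cpp_unet_nparams(model$ptr)
}

#' @export
print.eitsep_model <- function(x, ...) {
  cat("<eitsep_model>", x$architecture, "| input",
      x$spec$input_size, "| base filters", x$spec$base_filters,
      "| parameters", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.eitsep_dual <- function(x, ...) {
  cat("<eitsep_dual> two classical U-Nets | parameters",
      format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

# weight (de)serialization helpers: the native object is an external pointer
# and does not survive saveRDS, so fits keep plain weight vectors alongside
model_get_weights <- function(model) cpp_unet_get_weights(model$ptr)
model_set_weights <- function(model, w) {
  cpp_unet_set_weights(model$ptr, w)
  invisible(model)
}

# rebuild a model object of the same shape (fresh native instance)
rebuild_model <- function(model) {
  if (inherits(model, "eitsep_dual")) {
    return(build_dual_unet(model$spec, model$seed))
  }
  if (model$architecture == "semi_siamese") {
    build_semi_siamese(model$spec, model$seed)
  } else {
    build_classical_unet(model$spec, model$seed)
  }
}
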