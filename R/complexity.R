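# Parameter and FLOP accounting for convolutional layers and whole models.

#' Parameter count of a convolution layer
#'
#' `kd*kh*kw*(Cin/groups)*Cout`, plus `Cout` when a bias is present.
#' `groups = Cin = Cout` gives the depthwise case.
#'
#' @param kd,kh,kw Kernel extents.
#' @param cin,cout Input/output channel counts.
#' @param groups Convolution groups; must divide `cin` and `cout`.
#' @param bias Whether the layer has a bias term.
#' @return Parameter count (numeric scalar).
#' @export
conv_params <- function(kd, kh, kw, cin, cout, groups = 1L, bias = FALSE) {
  stopifnot(kd >= 1, kh >= 1, kw >= 1, cin >= 1, cout >= 1,
            cin %% groups == 0, cout %% groups == 0)
  kd * kh * kw * (cin / groups) * cout + if (bias) cout else 0
}

#' Floating-point operations of a convolution layer
#'
#' `ops_per_mac * kd*kh*kw*(Cin/groups)*Cout * d*h*w` for an output extent
#' `d x h x w`. With `ops_per_mac = 2` each multiply-accumulate counts as
#' two operations; `ops_per_mac = 1` is the fused convention used by the
#' model-comparison tables in the lightweight-segmentation literature.
#'
#' @inheritParams conv_params
#' @param d,h,w Output spatial extents.
#' @param ops_per_mac Operations counted per multiply-accumulate (2 or 1).
#' @return Operation count (numeric scalar).
#' @export
conv_flops <- function(kd, kh, kw, cin, cout, d, h, w, groups = 1L,
                       ops_per_mac = 2) {
  stopifnot(d >= 0, h >= 0, w >= 0)
  ops_per_mac * kd * kh * kw * (cin / groups) * cout * d * h * w
}

#' Model complexity report
#'
#' Walks every convolution and normalization layer of a built model and
#' reports exact parameter counts and convolutional operation counts at a
#' given input extent. Normalization, activation and pooling contribute
#' parameters (normalization affine terms) but no counted operations.
#' Totals are reported in millions (two decimals) and units of 1e9 (one
#' decimal), decimal scale.
#'
#' @param model An [hmnet_build()] model.
#' @param input_size Input extent per axis; defaults to the model's
#'   configured extent.
#' @param ops_per_mac 1 (fused multiply-accumulate, the reporting
#'   convention of the comparison tables this network is benchmarked in;
#'   default) or 2 (each multiply and add counted separately).
#' @return An `hmnet_complexity` object: per-layer tibble plus totals; see
#'   [tidy.hmnet_complexity()] and [glance.hmnet_complexity()].
#' @export
model_complexity <- function(model, input_size = model$config$input_size,
                             ops_per_mac = 1) {
  stopifnot(inherits(model, "hmnet_model"))
  layers <- model$layers
  voxels <- ifelse(is.na(layers$extent_div), 1,
                   (input_size / layers$extent_div)^3)
  layers$flops <- ops_per_mac * layers$macs_per_voxel * voxels
  layers$flops[layers$kind == "group_norm"] <- 0
  total_params <- sum(layers$n_params)
  total_flops <- sum(layers$flops)
  structure(list(
    layers = layers,
    input_size = as.integer(input_size),
    ops_per_mac = ops_per_mac,
    total_params = total_params,
    total_flops = total_flops,
    params_m = round(total_params / 1e6, 2),
    flops_g = round(total_flops / 1e9, 1)
  ), class = "hmnet_complexity")
}

#' @export
print.hmnet_complexity <- function(x, ...) {
  cat("<hmnet_complexity> input", x$input_size, "^3\n")
  cat(sprintf("  params: %s (%.2f M)\n", format(x$total_params, big.mark = ","),
              x$params_m))
  cat(sprintf("  flops:  %s (%.1f G, %d op%s per multiply-accumulate)\n",
              format(x$total_flops, big.mark = ",", scientific = FALSE),
              x$flops_g, x$ops_per_mac, if (x$ops_per_mac > 1) "s" else ""))
  invisible(x)
}

#' Per-layer complexity table
#'
#' @param x An `hmnet_complexity` object.
#' @param ... Unused.
#' @return A tibble with one row per layer: kernel, channels, groups,
#'   stride, output extent, parameters and counted operations.
#' @export
tidy.hmnet_complexity <- function(x, ...) {
  dplyr::mutate(x$layers,
                extent = ifelse(is.na(.data$extent_div), 1,
                                x$input_size / .data$extent_div))
}

#' One-row complexity summary
#'
#' @param x An `hmnet_complexity` object.
#' @param ... Unused.
#' @return A one-row tibble with total parameters and operations, raw and
#'   on the reported M / G scales.
#' @export
glance.hmnet_complexity <- function(x, ...) {
  tibble::tibble(
    input_size = x$input_size,
    n_layers = nrow(x$layers),
    total_params = x$total_params,
    total_flops = x$total_flops,
    params_m = x$params_m,
    flops_g = x$flops_g,
    ops_per_mac = x$ops_per_mac
  )
}
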