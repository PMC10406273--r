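#' Specification of the residual parcellation regressor
#'
#' Describes one network's 3D encoder/decoder regressor: an unpadded 3x3x3
#' stem convolution (1 -> `stem_channels`) followed by a sigmoid, three
#' residual encoder blocks (each several 3x3x3 convolutions with a
#' normalization layer after each, then max pooling with kernel 3 and stride
#' 1), dropout, three mirrored decoder blocks of 3x3x3 transposed
#' convolutions (each followed by normalization), a final transposed
#' convolution back to one channel and a terminal sigmoid. Parameter-free
#' additive skip connections join the stem output and each encoder-block
#' output to the decoder feature map with the identical channel-and-spatial
#' shape.
#'
#' Spatial bookkeeping: every unpadded convolution and every pooling layer
#' shrinks each spatial dimension by 2, and every transposed convolution
#' grows it by 2. Encoder block `b` therefore carries
#' `tconvs_per_decoder_block[mirror(b)] - 1` unpadded convolutions (the
#' remaining convolutions are shape-preserving), which keeps encoder and
#' decoder shapes mirror-symmetric for any block depth and makes the skip
#' additions well defined. Parameter counts do not depend on padding, so
#' this choice does not affect the parameter table.
#'
#' @param stem_channels Channels produced by the stem convolution.
#' @param encoder_channels Output channels of the three encoder blocks
#'   (strictly decreasing).
#' @param decoder_channels Output channels of the three decoder blocks; must
#'   mirror `c(stem_channels, encoder_channels[-3])` reversed.
#' @param convs_per_encoder_block Integer vector, convolutions per encoder
#'   block.
#' @param tconvs_per_decoder_block Integer vector, transposed convolutions
#'   per decoder block.
#' @param norm `"batch"` or `"instance"` normalization after each
#'   (transposed) convolution inside the blocks.
#' @param dropout_rate Dropout probability applied after the encoder and
#'   after the second decoder block.
#' @param batch_size_default Batch size used for reporting output shapes in
#'   [summarize_parameters()]; a runtime option, not part of the
#'   architecture.
#' @param use_skips Include the additive encoder-to-decoder skip
#'   connections (parameter-free, so the parameter table is unchanged).
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec()
#' m <- build_model(spec, c(53, 63, 52))
#' glance(summarize_parameters(m))
#' @export
model_spec <- function(stem_channels = 64L,
                       encoder_channels = c(32L, 16L, 8L),
                       decoder_channels = c(16L, 32L, 64L),
                       convs_per_encoder_block = c(3L, 3L, 3L),
                       tconvs_per_decoder_block = c(2L, 2L, 2L),
                       norm = c("batch", "instance"),
                       dropout_rate = 0.5,
                       batch_size_default = 5L,
                       use_skips = TRUE) {
  norm <- match.arg(norm)
  stopifnot(
    is_count(stem_channels),
    length(encoder_channels) == 3, all(diff(encoder_channels) < 0),
    length(decoder_channels) == 3, all(diff(decoder_channels) > 0),
    length(convs_per_encoder_block) == 3, all(convs_per_encoder_block >= 1),
    length(tconvs_per_decoder_block) == 3, all(tconvs_per_decoder_block >= 1),
    dropout_rate >= 0, dropout_rate < 1
  )
  if (!identical(as.integer(decoder_channels),
                 rev(as.integer(c(stem_channels, encoder_channels[-3]))))) {
    abort("decoder_channels must mirror c(stem_channels, encoder_channels[1:2]) reversed")
  }
  # unpadded convolutions in encoder block b, forced by decoder symmetry
  n_unpadded <- rev(as.integer(tconvs_per_decoder_block)) - 1L
  if (any(convs_per_encoder_block < pmax(n_unpadded, 1L))) {
    abort("convs_per_encoder_block too small for the mirrored decoder depth")
  }
  structure(
    list(
      in_channels = 1L,
      stem_channels = as.integer(stem_channels),
      encoder_channels = as.integer(encoder_channels),
      decoder_channels = as.integer(decoder_channels),
      convs_per_encoder_block = as.integer(convs_per_encoder_block),
      tconvs_per_decoder_block = as.integer(tconvs_per_decoder_block),
      n_unpadded_convs = n_unpadded,
      kernel_size = 3L,
      norm = norm,
      dropout_rate = dropout_rate,
      final_out_channels = 1L,
      batch_size_default = as.integer(batch_size_default),
      use_skips = isTRUE(use_skips)
    ),
    class = "model_spec"
  )
}

#' Ablation variants of the model specification
#'
#' Returns the specification for one of the four architecture-ablation
#' scenarios: the original configuration; `"S1"`, instance normalization in
#' place of batch normalization; `"S2"`, instance normalization with one
#' convolution removed from encoder block 1 and one transposed convolution
#' removed from the mirrored decoder block 3; `"S3"`, instance
#' normalization with one convolution / transposed convolution added at the
#' same sites. The removed/added encoder convolution is an unpadded one so
#' that encoder and decoder spatial shapes stay mirror-symmetric.
#'
#' @param spec A [model_spec()].
#' @param scenario One of `"original"`, `"S1"`, `"S2"`, `"S3"`.
#' @return A modified `model_spec`.
#' @export
ablation_variants <- function(spec, scenario = c("original", "S1", "S2", "S3")) {
  stopifnot(inherits(spec, "model_spec"))
  scenario <- match.arg(scenario)
  if (scenario == "original") return(spec)
  args <- list(
    stem_channels = spec$stem_channels,
    encoder_channels = spec$encoder_channels,
    decoder_channels = spec$decoder_channels,
    convs_per_encoder_block = spec$convs_per_encoder_block,
    tconvs_per_decoder_block = spec$tconvs_per_decoder_block,
    norm = "instance",
    dropout_rate = spec$dropout_rate,
    batch_size_default = spec$batch_size_default,
    use_skips = spec$use_skips
  )
  if (scenario == "S2") {
    args$convs_per_encoder_block[1] <- args$convs_per_encoder_block[1] - 1L
    args$tconvs_per_decoder_block[3] <- args$tconvs_per_decoder_block[3] - 1L
  } else if (scenario == "S3") {
    args$convs_per_encoder_block[1] <- args$convs_per_encoder_block[1] + 1L
    args$tconvs_per_decoder_block[3] <- args$tconvs_per_decoder_block[3] + 1L
  }
  do.call(model_spec, args)
}

# Flat execution plan for the fixed encoder/decoder topology. Each element
# is a primitive op; conv weights are named after the op.
model_plan <- function(spec) {
  plan <- list()
  add <- function(...) plan[[length(plan) + 1L]] <<- list(...)
  add(type = "conv", name = "stem", pad = 0L,
      cin = spec$in_channels, cout = spec$stem_channels)
  add(type = "sigmoid", name = "stem_act")
  add(type = "save_skip", tag = "s0")
  cin <- spec$stem_channels
  for (b in 1:3) {
    cout <- spec$encoder_channels[b]
    for (j in seq_len(spec$convs_per_encoder_block[b])) {
      pad <- if (j <= spec$n_unpadded_convs[b]) 0L else 1L
      add(type = "conv", name = sprintf("enc%d.conv%d", b, j), pad = pad,
          cin = if (j == 1) cin else cout, cout = cout)
      add(type = "norm", name = sprintf("enc%d.norm%d", b, j), channels = cout)
    }
    add(type = "pool", name = sprintf("enc%d.pool", b))
    if (b < 3) add(type = "save_skip", tag = paste0("s", b))
    cin <- cout
  }
  add(type = "dropout", name = "drop_enc")
  for (b in 1:3) {
    cout <- spec$decoder_channels[b]
    for (j in seq_len(spec$tconvs_per_decoder_block[b])) {
      add(type = "conv", name = sprintf("dec%d.tconv%d", b, j), pad = 2L,
          cin = if (j == 1) cin else cout, cout = cout)
      add(type = "norm", name = sprintf("dec%d.norm%d", b, j), channels = cout)
    }
    if (spec$use_skips) add(type = "add_skip", tag = paste0("s", 3L - b))
    if (b == 2) add(type = "dropout", name = "drop_dec")
    cin <- cout
  }
  add(type = "conv", name = "final", pad = 2L,
      cin = cin, cout = spec$final_out_channels)
  add(type = "sigmoid", name = "final_act")
  plan
}

# Spatial dimensions after each op; errors on underflow naming the layer.
plan_shapes <- function(plan, input_dims) {
  d <- as.integer(input_dims)
  shapes <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    op <- plan[[i]]
    if (op$type == "conv") {
      d <- d + 2L * op$pad - 2L
    } else if (op$type == "pool") {
      d <- d - 2L
    }
    if (any(d < 1L)) {
      abort(sprintf(
        "spatial underflow at layer '%s': dims would be %s; input %s is too small for this depth",
        op$name %||% op$type, fmt_dims(d), fmt_dims(input_dims)))
    }
    shapes[[i]] <- d
  }
  shapes
}

#' Build a residual parcellation model
#'
#' Instantiates the layer graph of a [model_spec()] for a given input grid,
#' validates that every layer keeps a positive spatial extent (reporting the
#' offending layer otherwise), and initializes all weights reproducibly
#' (Glorot-uniform convolutions, unit-gain normalization layers).
#'
#' @param spec A [model_spec()].
#' @param input_dims Integer vector of 3 voxel dimensions (default
#'   `c(53, 63, 52)`, the 3 mm standard-space grid).
#' @param init_seed Seed for weight initialization.
#' @param network_id Optional network identifier carried through to
#'   predictions and checkpoints.
#' @param out_bias_init Initial value of the final convolution's bias.
#'   Score-map targets are sparse (most voxels near 0), and with a terminal
#'   sigmoid a zero-initialized bias invites a saturation trap early in
#'   training; starting the bias near the logit of the expected target mean
#'   (default -3, i.e. a prior output around 0.05) is the standard
#'   initialization for sparse-target regression.
#' @return An object of class `parc_model`.
#' @export
build_model <- function(spec = model_spec(), input_dims = c(53L, 63L, 52L),
                        init_seed = 1L, network_id = NA_integer_,
                        out_bias_init = -3) {
  stopifnot(inherits(spec, "model_spec"), length(input_dims) == 3)
  input_dims <- as.integer(input_dims)
  plan <- model_plan(spec)
  shapes <- plan_shapes(plan, input_dims) # errors on underflow

  params <- list()
  state <- list()
  with_seed(init_seed, {
    for (op in plan) {
      if (op$type == "conv") {
        fan_in <- 27 * op$cin
        fan_out <- 27 * op$cout
        lim <- sqrt(6 / (fan_in + fan_out))
        w <- array(runif(27 * op$cin * op$cout, -lim, lim),
                   dim = c(3, 3, 3, op$cin, op$cout))
        params[[paste0(op$name, ".W")]] <- w
        params[[paste0(op$name, ".b")]] <- numeric(op$cout)
      } else if (op$type == "norm") {
        params[[paste0(op$name, ".gamma")]] <- rep(1, op$channels)
        params[[paste0(op$name, ".beta")]] <- numeric(op$channels)
        if (spec$norm == "batch") {
          state[[paste0(op$name, ".mean")]] <- numeric(op$channels)
          state[[paste0(op$name, ".var")]] <- rep(1, op$channels)
        }
      }
    }
  })
  params[["final.b"]][] <- out_bias_init

  structure(
    list(spec = spec, input_dims = input_dims, plan = plan, shapes = shapes,
         params = params, state = state, network_id = network_id),
    class = "parc_model"
  )
}

#' @export
print.parc_model <- function(x, ...) {
  s <- summarize_parameters(x)
  cat(sprintf("<parc_model> input %s, %s norm, %s trainable parameters\n",
              fmt_dims(x$input_dims), x$spec$norm,
              format(attr(s, "total_trainable"), big.mark = ",")))
  invisible(x)
}

#' Per-layer parameter accounting
#'
#' Summarizes the model as a table of layer/block rows with output shapes
#' and parameter counts, aggregating each encoder/decoder block into one row
#' (convolution and transposed-convolution layers contribute
#' `3^3 * C_in * C_out + C_out` parameters, normalization layers `2 * C`).
#' All parameters are trainable. The additive skip connections are
#' parameter-free and do not appear. Shapes are reported for
#' `spec$batch_size_default` as `[batch, channels, x, y, z]`.
#'
#' @param model A [build_model()] result.
#' @return A tibble of class `param_summary` with columns `layer`,
#'   `output_shape`, `params`, `trainable_params` and attributes `total`
#'   and `total_trainable`. Use [glance()] for the totals.
#' @export
summarize_parameters <- function(model) {
  stopifnot(inherits(model, "parc_model"))
  spec <- model$spec
  B <- spec$batch_size_default
  plan <- model$plan
  shapes <- model$shapes

  op_params <- function(op) {
    if (op$type == "conv") {
      length(model$params[[paste0(op$name, ".W")]]) +
        length(model$params[[paste0(op$name, ".b")]])
    } else if (op$type == "norm") {
      length(model$params[[paste0(op$name, ".gamma")]]) +
        length(model$params[[paste0(op$name, ".beta")]])
    } else 0L
  }
  op_channels <- function(op, i) {
    if (op$type == "conv") op$cout
    else if (op$type == "norm") op$channels
    else NA_integer_
  }

  rows <- list()
  n_row <- 0L
  emit <- function(kind, shape_dims, channels, params) {
    n_row <<- n_row + 1L
    rows[[length(rows) + 1L]] <<- tibble(
      layer = sprintf("%s-%d", kind, n_row),
      output_shape = sprintf("[%s]", paste(c(B, channels, shape_dims),
                                           collapse = ", ")),
      params = as.integer(params),
      trainable_params = as.integer(params)
    )
  }

  i <- 1L
  while (i <= length(plan)) {
    op <- plan[[i]]
    nm <- op$name %||% ""
    if (identical(nm, "stem")) {
      emit("Conv3d", shapes[[i]], op$cout, op_params(op))
    } else if (op$type == "sigmoid") {
      ch <- if (identical(nm, "stem_act")) spec$stem_channels else spec$final_out_channels
      emit("Sigmoid", shapes[[i]], ch, 0L)
    } else if (grepl("^enc[0-9]+\\.conv1$", nm) || grepl("^dec[0-9]+\\.tconv1$", nm)) {
      # aggregate the whole block up to (and including) its pool, if any
      block <- sub("\\..*$", "", nm)
      total <- 0L
      j <- i
      while (j <= length(plan) &&
             (startsWith(plan[[j]]$name %||% "", paste0(block, ".")))) {
        total <- total + op_params(plan[[j]])
        j <- j + 1L
      }
      kind <- if (startsWith(block, "enc")) "ResEncBlocks" else "ResDecBlocks"
      emit(kind, shapes[[j - 1L]],
           if (startsWith(block, "enc")) {
             spec$encoder_channels[as.integer(sub("enc", "", block))]
           } else {
             spec$decoder_channels[as.integer(sub("dec", "", block))]
           },
           total)
      i <- j
      next
    } else if (op$type == "dropout") {
      emit("Dropout3d", shapes[[i]],
           if (identical(nm, "drop_enc")) spec$encoder_channels[3] else spec$decoder_channels[2],
           0L)
    } else if (identical(nm, "final")) {
      emit("ConvTranspose3d", shapes[[i]], op$cout, op_params(op))
    }
    i <- i + 1L
  }

  out <- dplyr::bind_rows(rows)
  total <- sum(vapply(plan, op_params, numeric(1)))
  attr(out, "total") <- as.integer(total)
  attr(out, "total_trainable") <- as.integer(total)
  class(out) <- c("param_summary", class(out))
  out
}

#' @export
#' @method glance param_summary
glance.param_summary <- function(x, ...) {
  tibble(total = attr(x, "total"),
         total_trainable = attr(x, "total_trainable"),
         non_trainable = attr(x, "total") - attr(x, "total_trainable"))
}

#' @export
#' @method glance parc_model
glance.parc_model <- function(x, ...) {
  s <- summarize_parameters(x)
  dplyr::bind_cols(
    tibble(input_dims = fmt_dims(x$input_dims), norm = x$spec$norm),
    glance(s)
  )
}

#' Write the parameter table as TSV
#'
#' @param summary A [summarize_parameters()] result.
#' @param path Output file.
#' @export
write_param_table <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat(sprintf("Total params: %s\nTrainable params: %s\n",
              attr(summary, "total"), attr(summary, "total_trainable")),
      file = path, append = TRUE)
  invisible(path)
}
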