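## Analytic cost accounting. The profiler walks the same graph definition
## the forward pass executes, so the reported multiply-accumulate counts are
## exactly the arithmetic the engine performs. Convention: 1 MAC = 1 FLOP
## (the scale under which ResNet50 costs ~3.8-4.1 GFLOPs per 224x224 image);
## normalisation, activation and pooling are counted as zero.

#' Analytic FLOP count of an architecture
#'
#' @param spec an [arch_spec()]; its `input_size` is overridden by
#'   `input_size` here.
#' @param input_size `c(H, W)` inference resolution.
#' @param batch batch size; the total is linear in it.
#' @return object of class `flop_report` with `total_macs`, `gflops`
#'   (`total_macs / 1e9`) and a per-layer breakdown that sums to the total.
#' @export
count_flops <- function(spec, input_size = c(224, 224), batch = 64) {
  if (!inherits(spec, "arch_spec")) stop("spec must be an arch_spec")
  spec2 <- spec
  spec2$input_size <- as.integer(rep(input_size, length.out = 2))
  g <- arch_graph(spec2, init_params = FALSE)
  ids <- character(0); ops <- character(0); macs <- numeric(0)
  for (node in g$nodes) {
    m <- switch(node$op,
      conv = {
        os <- g$shapes[[node$id]]
        (node$hyper$cin / node$hyper$groups) * node$hyper$cout *
          node$hyper$k^2 * os[1] * os[2]
      },
      linear = node$hyper$fin * node$hyper$fout,
      bn = , act = , maxpool2 = , gap = , add = , concat = ,
      upsample2 = , dropout = , sescale = 0,
      err(paste0("cannot profile layer type: ", node$op),
          "endoscreen_profiling_error"))
    if (m > 0) {
      ids <- c(ids, node$id); ops <- c(ops, node$op); macs <- c(macs, m)
    }
  }
  total <- sum(macs) * batch
  structure(list(arch = spec$name,
                 input_size = spec2$input_size, batch = as.integer(batch),
                 total_macs = total, gflops = total / 1e9,
                 breakdown = data.frame(layer = ids, op = ops,
                                        macs = macs * batch,
                                        stringsAsFactors = FALSE)),
            class = "flop_report")
}

#' @export
print.flop_report <- function(x, ...) {
  cat(sprintf("<flop_report> %s @ %dx%d, batch %d: %.2f GFLOPs (%d layers)\n",
              x$arch, x$input_size[1], x$input_size[2], x$batch, x$gflops,
              nrow(x$breakdown)))
  invisible(x)
}

#' Wall-clock inference timing (informational)
#'
#' Runs random batches through a classifier and reports the median of
#' `repeats` timed passes after `warmup` untimed ones. Hardware-dependent;
#' use for relative comparisons on the same host only.
#'
#' @param model an `endo_classifier` (trained or freshly built).
#' @param batch_size images per pass.
#' @param repeats,warmup number of timed / discarded passes.
#' @return list with `raw` timings (seconds), their `median`, and a
#'   `hardware` descriptor.
#' @export
time_inference <- function(model, batch_size = 8, repeats = 5, warmup = 1) {
  sz <- model$spec$input_size
  x <- array(stats::runif(sz[1] * sz[2] * 3 * batch_size),
             c(sz[1], sz[2], 3, batch_size))
  for (i in seq_len(warmup)) nn_forward(model$graph, x)
  raw <- vapply(seq_len(repeats), function(i) {
    t0 <- proc.time()[["elapsed"]]
    nn_forward(model$graph, x)
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  list(raw = raw, median = stats::median(raw), batch_size = batch_size,
       hardware = paste(R.version$platform, "| 1 thread BLAS unknown"))
}
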