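## Encoder f(.) and projection head g(.).
##
## The encoder follows the residual template: an initial 1-D convolution +
## batch normalization + ReLU + max pooling, then a chain of residual blocks
## (two conv/BN/ReLU stages with an additive skip path, downsampling per
## block), then global average pooling over time, yielding a representation
## vector whose width equals the final stage's channel count. The full-size
## default (4,096 x 12 input, kernel width 16, 4 blocks with channels
## 64-128-196-256-320, downsample 4 per block) yields 320-dimensional
## representations; every element is configurable so desk-scale instances
## can be trained quickly.

#' Encoder configuration
#'
#' @param inputLength Samples per lead the encoder consumes (default 4,096).
#' @param nLeads Number of leads (default 12).
#' @param convFilterSize Kernel width of every convolution (default 16).
#' @param channelsPerStage Channel widths: the first entry is the stem output
#'   width, each following entry one residual block's width; the last entry
#'   is the representation width (default `c(64, 128, 196, 256, 320)`).
#' @param nResidualBlocks Number of residual blocks; must equal
#'   `length(channelsPerStage) - 1`.
#' @param representationDim Width of the representation `h`; must equal the
#'   last entry of `channelsPerStage` (default 320).
#' @param downsamplePerBlock Temporal downsampling factor of each residual
#'   block (default 4).
#' @param stemPool Max-pool factor after the initial convolution (default 2).
#' @return Validated config list of class `encoderConfig`.
#' @export
encoderConfig <- function(inputLength = 4096L, nLeads = 12L,
                          convFilterSize = 16L,
                          channelsPerStage = c(64L, 128L, 196L, 256L, 320L),
                          nResidualBlocks = length(channelsPerStage) - 1L,
                          representationDim = channelsPerStage[length(channelsPerStage)],
                          downsamplePerBlock = 4L, stemPool = 2L) {
  cfg <- list(inputLength = as.integer(inputLength), nLeads = as.integer(nLeads),
              convFilterSize = as.integer(convFilterSize),
              channelsPerStage = as.integer(channelsPerStage),
              nResidualBlocks = as.integer(nResidualBlocks),
              representationDim = as.integer(representationDim),
              downsamplePerBlock = as.integer(downsamplePerBlock),
              stemPool = as.integer(stemPool))
  if (cfg$convFilterSize < 1 || any(cfg$channelsPerStage < 1) ||
      cfg$inputLength < 1 || cfg$nLeads < 1 || cfg$downsamplePerBlock < 1 ||
      cfg$stemPool < 1) {
    pclrError("encoder config: all counts must be >= 1", "pclr_config_error")
  }
  if (cfg$nResidualBlocks != length(cfg$channelsPerStage) - 1L) {
    pclrError("encoder config: need one stem width plus one channel width per block",
              "pclr_config_error")
  }
  if (cfg$representationDim != cfg$channelsPerStage[length(cfg$channelsPerStage)]) {
    pclrError("encoder config: representationDim must equal the last channel width",
              "pclr_config_error")
  }
  chain <- cfg$stemPool * cfg$downsamplePerBlock^cfg$nResidualBlocks
  if (cfg$inputLength %% chain != 0) {
    pclrError(sprintf(
      "encoder config: input length %d not divisible through the downsampling chain (factor %d)",
      cfg$inputLength, chain), "pclr_config_error")
  }
  class(cfg) <- c("encoderConfig", "list")
  cfg
}

#' Projection head configuration
#'
#' Dense(hidden) -> ReLU -> Dense(output), no activation after the final
#' layer; defaults are 320 hidden and 320 output units.
#'
#' @param inputDim Width of the incoming representation (default 320).
#' @param hiddenUnits Hidden layer width (default 320).
#' @param outputUnits Output (projection) width (default 320).
#' @return Validated config list of class `projectionConfig`.
#' @export
projectionConfig <- function(inputDim = 320L, hiddenUnits = 320L,
                             outputUnits = 320L) {
  cfg <- list(inputDim = as.integer(inputDim),
              hiddenUnits = as.integer(hiddenUnits),
              outputUnits = as.integer(outputUnits))
  if (any(unlist(cfg) < 1)) {
    pclrError("projection config: all counts must be >= 1", "pclr_config_error")
  }
  class(cfg) <- c("projectionConfig", "list")
  cfg
}

#' Build the ECG encoder
#'
#' Constructs the residual convolutional encoder described by `config`, with
#' weights drawn from `seed` (He-normal initialization). The returned object
#' maps preprocessed ECG tensors to `representationDim`-wide vectors via
#' global average pooling over the final feature map; an input length that
#' does not survive the downsampling chain is rejected at build time.
#'
#' @param config An [encoderConfig()].
#' @param seed Integer seed for weight initialization.
#' @param dropoutRate Dropout rate applied after each in-block convolution
#'   stage (used by the supervised from-scratch baseline; default 0).
#' @return An [ECGEncoder-class].
#' @examples
#' enc <- buildEncoder(encoderConfig(inputLength = 256,
#'   channelsPerStage = c(8, 16), downsamplePerBlock = 4), seed = 1)
#' @export
buildEncoder <- function(config, seed = 1L, dropoutRate = 0) {
  stopifnot(inherits(config, "encoderConfig"))
  withSeed(deriveSeed(seed, 11), {
    ch <- config$channelsPerStage
    t <- config$inputLength
    layers <- list(
      layerConv(config$nLeads, ch[1], config$convFilterSize, 1L, t),
      layerBN(ch[1]), layerReLU(),
      layerMaxPool(config$stemPool, t)
    )
    t <- t %/% config$stemPool
    for (b in seq_len(config$nResidualBlocks)) {
      blk <- resBlock(ch[b], ch[b + 1], config$convFilterSize,
                      config$downsamplePerBlock, t)
      if (dropoutRate > 0) {
        ## dropout on the convolutional stages, inserted after each in-block ReLU
        blk$main <- append(blk$main, list(layerDropout(dropoutRate)), after = 3L)
      }
      layers <- c(layers, list(blk))
      t <- t %/% config$downsamplePerBlock
    }
    layers <- c(layers, list(layerGAP()))
    new("ECGEncoder", config = unclass(config), net = layers)
  })
}

#' Build the projection head
#'
#' @param config A [projectionConfig()].
#' @param seed Integer seed for weight initialization.
#' @return A [ProjectionHead-class].
#' @export
buildProjectionHead <- function(config, seed = 1L) {
  stopifnot(inherits(config, "projectionConfig"))
  withSeed(deriveSeed(seed, 13), {
    layers <- list(
      layerDense(config$inputDim, config$hiddenUnits),
      layerReLU(),
      layerDense(config$hiddenUnits, config$outputUnits)
    )
    new("ProjectionHead", config = unclass(config), net = layers)
  })
}

## Coerce input to a (batch, time, leads) array.
asBatchArray <- function(x) {
  if (is(x, "ECGTensorSet")) return(aperm(x@tensors, c(3, 1, 2)))
  if (is.matrix(x)) {
    a <- array(x, c(1, nrow(x), ncol(x)))
    return(a)
  }
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("input must be an ECGTensorSet, a samples x leads matrix, or a 3-D array")
}

#' Encode ECGs into representations
#'
#' Runs the encoder forward (inference mode: batch-norm uses running
#' statistics, dropout inactive) and returns one representation row per
#' record.
#'
#' @param encoder An [ECGEncoder-class].
#' @param x An [ECGTensorSet-class], a single `samples x 12` matrix, or a
#'   `batch x samples x 12` array.
#' @param batchSize Records per forward chunk (memory control).
#' @return Numeric matrix `n x representationDim`.
#' @export
encode <- function(encoder, x, batchSize = 64L) {
  stopifnot(is(encoder, "ECGEncoder"))
  X <- asBatchArray(x)
  n <- dim(X)[1]
  out <- matrix(0, n, encoder@config$representationDim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    r <- seqForward(encoder@net, X[i:j, , , drop = FALSE],
                    training = FALSE, needGrad = FALSE)
    out[i:j, ] <- r$out
    i <- j + 1L
  }
  out
}

#' Project representations
#'
#' Applies the projection head g(.) to representation rows; used only during
#' pre-training.
#'
#' @param head A [ProjectionHead-class].
#' @param h Numeric matrix `n x inputDim` of representations.
#' @return Numeric matrix `n x outputUnits` of projections.
#' @export
project <- function(head, h) {
  stopifnot(is(head, "ProjectionHead"))
  if (ncol(h) != head@config$inputDim) {
    pclrError(sprintf("projection head expects width %d, got %d",
                      head@config$inputDim, ncol(h)), "pclr_width_mismatch")
  }
  seqForward(head@net, h, training = FALSE, needGrad = FALSE)$out
}

#' Describe a model's layers
#'
#' Prints (and invisibly returns) a plain-text layer summary with the total
#' parameter count, for auditing an architecture configuration.
#'
#' @param x An [ECGEncoder-class] or [ProjectionHead-class].
#' @return Character vector of layer descriptions, invisibly.
#' @export
describeModel <- function(x) {
  net <- if (is(x, "ECGEncoder") || is(x, "ProjectionHead")) x@net else x
  lines <- c(describeLayers(net),
             sprintf("Total parameters: %d", countParams(net)))
  cat(lines, sep = "\n")
  invisible(lines)
}

setMethod("show", "ECGEncoder", function(object) {
  cat(sprintf("ECGEncoder: %d x %d -> %d (%d parameters)\n",
              object@config$inputLength, object@config$nLeads,
              object@config$representationDim, countParams(object@net)))
})

setMethod("show", "ProjectionHead", function(object) {
  cat(sprintf("ProjectionHead: %d -> %d -> %d\n", object@config$inputDim,
              object@config$hiddenUnits, object@config$outputUnits))
})
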