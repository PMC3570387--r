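# Data-processing chain for raw log2 arrays: probe quality-flag filtering,
# M-A loess normalization against a virtual median reference array, and
# virtual-median log2 ratios z-transformed within each array.

#' Filter genes by probe quality flags
#'
#' Retains exactly the genes flagged \code{"Good"} on at least
#' \code{minGoodFraction} of the arrays (default 90%), preserving gene
#' order. Genes below the threshold are dropped from both the values and
#' the flag matrix.
#'
#' @param values genes x arrays numeric matrix.
#' @param flags same-shape character matrix of quality verdicts; entries
#'   equal to \code{"Good"} count as good.
#' @param minGoodFraction minimum fraction of Good flags to retain a gene.
#' @return list with the filtered \code{values} and \code{flags} matrices
#'   and the logical vector \code{kept} over the input genes.
#' @examples
#' v <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' f <- matrix("Good", 4, 5); f[1, 1:3] <- "Bad"
#' filterFlags(v, f, 0.9)$kept
#' @export
filterFlags <- function(values, flags, minGoodFraction = 0.9) {
  if (is.null(flags))
    stop("no flag matrix supplied; to bypass quality filtering, skip this ",
         "step explicitly rather than passing flags = NULL")
  stopifnot(identical(dim(values), dim(flags)),
            minGoodFraction >= 0, minGoodFraction <= 1)
  goodFrac <- rowMeans(flags == "Good")
  kept <- goodFrac >= minGoodFraction
  list(values = values[kept, , drop = FALSE],
       flags = flags[kept, , drop = FALSE],
       kept = kept)
}

#' Loess-normalize arrays against a virtual median reference
#'
#' For each array, computes M = value - reference and
#' A = (value + reference)/2 against the virtual reference array (the
#' per-gene median across all arrays), fits a degree-1 loess trend of M on
#' A, and subtracts the fitted trend from the array. This removes
#' intensity-dependent bias; an input free of such bias is returned
#' essentially unchanged, and the operation is idempotent up to the loess
#' fitting tolerance.
#'
#' @param values genes x arrays matrix on the log2 scale.
#' @param span loess span (default 0.4).
#' @param minGenes minimum number of genes required for a reliable fit.
#' @return the normalized matrix, same shape and dimnames.
#' @examples
#' v <- matrix(rnorm(600, 8), 100, 6,
#'             dimnames = list(sprintf("g%03d", 1:100), paste0("a", 1:6)))
#' norm <- loessNormalize(v)
#' @export
loessNormalize <- function(values, span = 0.4, minGenes = 50L) {
  if (nrow(values) < minGenes)
    stop(sprintf("loess normalization needs >= %d genes (got %d): %s",
                 minGenes, nrow(values),
                 "the trend fit is unreliable on fewer"))
  ref <- apply(values, 1, stats::median)
  out <- values
  for (j in seq_len(ncol(values))) {
    M <- values[, j] - ref
    A <- (values[, j] + ref) / 2
    fit <- limma::loessFit(M, A, span = span)
    out[, j] <- values[, j] - fit$fitted
  }
  out
}

#' Within-array z-scores of log2 ratios against a virtual median array
#'
#' Computes the virtual median array (per-gene median across arrays),
#' subtracts it from each array to obtain log2 ratios, then z-transforms
#' the ratios within each array: each column is centred on its own mean
#' ratio and scaled by its sample (n-1) standard deviation across genes.
#' Every output column therefore has mean 0 and sd 1.
#'
#' @param values genes x arrays matrix on the log2 scale (>= 2 arrays).
#' @param target named character vector mapping every array identifier to
#'   the gene its siRNA targeted, or an unnamed vector in column order.
#'   May also be a raw disruptant \code{SummarizedExperiment} from
#'   [simulateDisruptants()] in place of \code{values}, in which case
#'   \code{target} is taken from its \code{colData}.
#' @return A \linkS4class{DisruptantPanel} with assays \code{z} and
#'   \code{log2}.
#' @examples
#' v <- cbind(a1 = c(0, 0), a2 = c(2, 0), a3 = c(4, 0))
#' rownames(v) <- c("g1", "g2")
#' try(toZPanel(v, c(a1 = "g1", a2 = "g1", a3 = "g2")))  # a3 ratio sd may be 0
#' @export
toZPanel <- function(values, target) {
  if (is(values, "SummarizedExperiment")) {
    se <- values
    values <- assay(se, "log2")
    if (missing(target)) target <- targetMap(se)
  }
  if (ncol(values) < 2) stop("need >= 2 arrays to form a virtual median array")
  if (is.null(names(target))) {
    stopifnot(length(target) == ncol(values))
    names(target) <- colnames(values)
  }
  missingMap <- setdiff(colnames(values), names(target))
  if (length(missingMap))
    stop("arrays without a target-map entry: ",
         paste(missingMap, collapse = ", "))
  target <- target[colnames(values)]
  med <- apply(values, 1, stats::median)
  ratio <- values - med
  sdv <- apply(ratio, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero ratio variance in array(s): ",
         paste(colnames(values)[sdv == 0], collapse = ", "))
  z <- scale(ratio, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  se <- SummarizedExperiment(
    assays = list(z = z, log2 = values),
    colData = DataFrame(target = unname(target), row.names = colnames(values)))
  new("DisruptantPanel", se)
}
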