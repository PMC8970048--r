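#' @import methods
#' @importFrom stats rnorm runif sd var cov fft predict
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib tomogan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TomoVolume: a cubic 3D grayscale volume
#'
#' Container for one cubic volume (an experimental-style subtomogram or a
#' clean macromolecule density map). Values are stored as a numeric
#' \code{n x n x n} array; the voxel spacing is in nanometres.
#'
#' @slot data numeric rank-3 array with equal extents.
#' @slot voxelSpacing numeric(1), nm per voxel (default 1).
#' @slot provenance free-text tag describing how the volume was produced.
#' @export
setClass("TomoVolume",
  representation(data = "array", voxelSpacing = "numeric", provenance = "character"),
  prototype(voxelSpacing = 1.0, provenance = "")
)

setValidity("TomoVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a rank-3 array")
  if (length(unique(d)) != 1L) {
    return(sprintf("volume grid must be cubic; got %s", paste(d, collapse = " x ")))
  }
  if (!all(is.finite(object@data))) return("volume contains non-finite values")
  if (length(object@voxelSpacing) != 1L || !is.finite(object@voxelSpacing) ||
      object@voxelSpacing <= 0) {
    return("voxelSpacing must be a single positive number")
  }
  TRUE
})

#' Construct a TomoVolume
#'
#' @param data cubic numeric array (n x n x n).
#' @param voxelSpacing voxel edge length in nm.
#' @param provenance free-text provenance tag.
#' @return A \linkS4class{TomoVolume}.
#' @examples
#' v <- TomoVolume(array(0, c(8, 8, 8)))
#' sideLength(v)
#' @export
TomoVolume <- function(data, voxelSpacing = 1.0, provenance = "") {
  new("TomoVolume", data = data, voxelSpacing = as.numeric(voxelSpacing),
      provenance = as.character(provenance)[1])
}

#' DomainDataset: an unpaired collection of volumes from one domain
#'
#' Holds the volumes of one translation domain: \code{"S"} (experimental-style
#' subtomograms) or \code{"D"} (clean density maps). Labels, when present,
#' give a class tag per volume.
#'
#' @slot volumes list of \linkS4class{TomoVolume}, all with one side length.
#' @slot domain \code{"S"} or \code{"D"}.
#' @slot labels character vector of per-volume class tags, or length 0.
#' @slot manifestPath path of the manifest the dataset was read from ("" if none).
#' @export
setClass("DomainDataset",
  representation(volumes = "list", domain = "character", labels = "character",
                 manifestPath = "character"),
  prototype(labels = character(0), manifestPath = "")
)

setValidity("DomainDataset", function(object) {
  if (!object@domain %in% c("S", "D")) return("domain must be 'S' or 'D'")
  if (!all(vapply(object@volumes, is, logical(1), "TomoVolume"))) {
    return("volumes must all be TomoVolume objects")
  }
  if (length(object@volumes) > 0) {
    ns <- vapply(object@volumes, function(v) dim(v@data)[1], integer(1))
    if (length(unique(ns)) != 1L) return("all volumes must share one side length")
  }
  if (length(object@labels) > 0 && length(object@labels) != length(object@volumes)) {
    return("labels, when present, must cover every volume")
  }
  TRUE
})

#' Construct a DomainDataset
#'
#' @param volumes list of \linkS4class{TomoVolume}.
#' @param domain domain tag, \code{"S"} or \code{"D"}.
#' @param labels optional character vector of class labels (one per volume).
#' @param manifestPath optional path of the originating manifest.
#' @return A \linkS4class{DomainDataset}.
#' @export
DomainDataset <- function(volumes, domain, labels = character(0), manifestPath = "") {
  new("DomainDataset", volumes = volumes, domain = domain,
      labels = as.character(labels), manifestPath = manifestPath)
}

#' TranslationModel: paired generators and critics for unpaired translation
#'
#' The four networks of the cycle-consistent adversarial translation model:
#' generator \code{gds} (density map to subtomogram), generator \code{gsd}
#' (subtomogram to density map), and critics \code{da} (scores subtomograms)
#' and \code{db} (scores density maps). Networks are parameter lists consumed
#' by the internal forward/backward engine; access them through
#' \code{\link{generateVolume}}, \code{\link{trainTranslation}} and friends.
#'
#' @slot gds,gsd generator networks (density->subtomogram, subtomogram->density).
#' @slot da,db critic networks for the S and D domains.
#' @slot n input side length in voxels.
#' @slot baseFilters width of the first generator stage (paper-scale plan: 32).
#' @slot dropoutRate dropout probability in generator residual blocks.
#' @slot spectralNorm logical; spectral normalization on critic convolutions.
#' @export
setClass("TranslationModel",
  representation(gds = "list", gsd = "list", da = "list", db = "list",
                 n = "integer", baseFilters = "integer", dropoutRate = "numeric",
                 spectralNorm = "logical")
)

#' UncertaintyMap: per-voxel standard deviation over stochastic generations
#'
#' @slot stdMap rank-3 array of per-voxel standard deviations (population
#'   convention, divide by the number of draws).
#' @slot nSamples number of Monte-Carlo draws.
#' @slot source free-text reference to the input density map.
#' @export
setClass("UncertaintyMap",
  representation(stdMap = "array", nSamples = "integer", source = "character")
)

setValidity("UncertaintyMap", function(object) {
  if (length(dim(object@stdMap)) != 3L) return("stdMap must be rank-3")
  if (any(object@stdMap < 0)) return("stdMap must be nonnegative")
  if (object@nSamples < 2L) return("nSamples must be >= 2")
  TRUE
})

#' EmbeddingSet: a matrix of feature vectors
#'
#' Rows are embedded samples (real \code{X_i} or generated \code{Y_j});
#' columns are feature dimensions.
#'
#' @slot vectors numeric N x d matrix.
#' @slot source tag, e.g. "real" or "generated".
#' @export
setClass("EmbeddingSet",
  representation(vectors = "matrix", source = "character"),
  prototype(source = "")
)

setValidity("EmbeddingSet", function(object) {
  if (!all(is.finite(object@vectors))) return("embeddings must be finite")
  TRUE
})

#' Construct an EmbeddingSet
#' @param vectors numeric matrix, one row per sample.
#' @param source free-text tag.
#' @return An \linkS4class{EmbeddingSet}.
#' @export
EmbeddingSet <- function(vectors, source = "") {
  new("EmbeddingSet", vectors = as.matrix(vectors), source = source)
}

# ---- generics & accessors ----------------------------------------------------

#' Accessors for tomogan classes
#'
#' @param x an object of the documented class.
#' @return \code{volumeData}: the numeric array; \code{voxelSpacing}: nm per
#'   voxel; \code{sideLength}: side in voxels; \code{volumes}: list of
#'   volumes; \code{domainTag}: "S" or "D"; \code{volumeLabels}: class labels;
#'   \code{stdMap}: the uncertainty array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "TomoVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TomoVolume", function(x) x@voxelSpacing)

#' @rdname accessors
#' @export
setGeneric("sideLength", function(x) standardGeneric("sideLength"))
#' @rdname accessors
#' @export
setMethod("sideLength", "TomoVolume", function(x) dim(x@data)[1])
#' @rdname accessors
#' @export
setMethod("sideLength", "DomainDataset", function(x) {
  if (length(x@volumes) == 0) return(NA_integer_)
  dim(x@volumes[[1]]@data)[1]
})

#' @rdname accessors
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))
#' @rdname accessors
#' @export
setMethod("volumes", "DomainDataset", function(x) x@volumes)

#' @rdname accessors
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))
#' @rdname accessors
#' @export
setMethod("domainTag", "DomainDataset", function(x) x@domain)

#' @rdname accessors
#' @export
setGeneric("volumeLabels", function(x) standardGeneric("volumeLabels"))
#' @rdname accessors
#' @export
setMethod("volumeLabels", "DomainDataset", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("stdMap", function(x) standardGeneric("stdMap"))
#' @rdname accessors
#' @export
setMethod("stdMap", "UncertaintyMap", function(x) x@stdMap)

#' @param object object to display.
#' @rdname accessors
#' @export
setMethod("show", "TomoVolume", function(object) {
  n <- dim(object@data)[1]
  cat(sprintf("TomoVolume %d^3, spacing %.3g nm, range [%.3g, %.3g]%s\n",
              n, object@voxelSpacing, min(object@data), max(object@data),
              if (nzchar(object@provenance)) paste0(" <", object@provenance, ">") else ""))
})

#' @rdname accessors
#' @export
setMethod("show", "DomainDataset", function(object) {
  cat(sprintf("DomainDataset '%s': %d volumes of side %s%s\n",
              object@domain, length(object@volumes), sideLength(object),
              if (length(object@labels)) sprintf(", %d classes",
                length(unique(object@labels))) else ", unlabeled"))
})

#' @rdname accessors
#' @export
setMethod("show", "TranslationModel", function(object) {
  cat(sprintf(
    "TranslationModel n=%d, base filters %d, dropout %.2g, spectral norm %s\n",
    object@n, object@baseFilters, object@dropoutRate,
    if (object@spectralNorm) "on" else "off"))
  cat(sprintf("  parameters: G_ds %d, G_sd %d, D_A %d, D_B %d\n",
              countParams(object@gds), countParams(object@gsd),
              countParams(object@da), countParams(object@db)))
})

#' @rdname accessors
#' @export
setMethod("show", "UncertaintyMap", function(object) {
  cat(sprintf("UncertaintyMap %d^3 over %d draws; mean std %.4g, max %.4g\n",
              dim(object@stdMap)[1], object@nSamples,
              mean(object@stdMap), max(object@stdMap)))
})
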