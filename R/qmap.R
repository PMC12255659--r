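#' Quantitative susceptibility map container
#'
#' A `qmap` bundles one 3-D volume of susceptibility values (chi, in ppm)
#' with a validity mask and the voxel size in mm. Values inside the mask
#' must be finite; values outside the mask are ignored by all metrics.
#'
#' @param values 3-D numeric array of susceptibility in ppm.
#' @param mask Logical array of the same shape, or `NULL` for an all-true
#'   mask.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#'
#' @return An object of class `qmap`: a list with elements `values`,
#'   `mask` and `voxel_size`.
#' @export
#' @examples
#' q <- qmap(array(rnorm(8^3, sd = 0.01), c(8, 8, 8)))
#' dim(q$values)
qmap <- function(values, mask = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim(values))
  }
  if (!identical(dim(mask), dim(values))) {
    stop("`mask` shape must match `values` shape", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim(mask))
  if (any(!is.finite(values[mask]))) {
    stop("non-finite susceptibility values inside the mask", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (mm)", call. = FALSE)
  }
  structure(
    list(values = values, mask = mask, voxel_size = voxel_size),
    class = "qmap"
  )
}

#' @export
print.qmap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<qmap> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d masked-in\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    sum(x$mask)
  ))
  v <- x$values[x$mask]
  cat(sprintf(
    "  chi [ppm]: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
    mean(v), stats::sd(v), min(v), max(v)
  ))
  invisible(x)
}

# Coerce a qmap or bare array to a numeric 3-D array.
as_volume <- function(x) {
  if (inherits(x, "qmap")) x$values else x
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation helpers do not disturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific child seed from a parent seed, staying inside
# the 32-bit signed integer range R requires.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}
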