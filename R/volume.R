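#' Image volume container
#'
#' A minimal container for one subject's 3D scalar grid for one image
#' channel: the voxel data, the voxel spacing in mm, and the channel label.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm numeric length-3, positive voxel spacing in mm.
#' @param channel channel label, one of `"T1w"`, `"PD"`, `"MT"`, `"R1"`,
#'   `"R2*"`, `"FLAIR"`.
#' @return An object of class `ms_volume`.
#' @export
volume <- function(data, voxel_size_mm = c(1, 1, 1), channel = "T1w") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L, length(voxel_size_mm) == 3L,
            all(voxel_size_mm > 0))
  channel <- match.arg(channel, c("T1w", "PD", "MT", "R1", "R2*", "FLAIR"))
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 channel = channel),
            class = "ms_volume")
}

#' @export
print.ms_volume <- function(x, ...) {
  cat(sprintf("<ms_volume> channel=%s dim=%s voxel=%s mm\n", x$channel,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

as_volume <- function(x, channel = "T1w", voxel_size_mm = c(1, 1, 1)) {
  if (inherits(x, "ms_volume")) x else volume(x, voxel_size_mm, channel)
}

voxel_volume_mm3 <- function(v) prod(v$voxel_size_mm)
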