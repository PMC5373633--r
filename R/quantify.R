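# Per-nucleus intensity measurement from a label mask and the two channels.

#' Measure per-nucleus signal and DNA-content proxies
#'
#' For every labelled object: centroid, area, the arithmetic mean of raw
#' replication-channel pixel values over the nucleus footprint
#' (`signal_mean`, the "average nuclear signal"), and the mean and sum of
#' DAPI intensities (`dapi_mean`, `dapi_integrated`; the integrated DAPI
#' signal proxies DNA content). Raw pixel values are used throughout — no
#' background subtraction or illumination correction.
#'
#' @param labels Integer label matrix (0 = background).
#' @param signal_image Replication-channel intensity matrix, same size.
#' @param dapi_image DAPI-channel intensity matrix, same size.
#' @return A `data.frame` with one row per label: `nucleus_id`,
#'   `centroid_row`, `centroid_col`, `area`, `signal_mean`, `dapi_mean`,
#'   `dapi_integrated`. Empty mask gives an empty table.
#' @export
measure_nuclei <- function(labels, signal_image, dapi_image) {
  if (!all(dim(labels) == dim(signal_image)) ||
      !all(dim(labels) == dim(dapi_image)))
    stop("labels, signal_image and dapi_image must share dimensions")
  nz <- which(labels > 0L)
  empty <- data.frame(nucleus_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area = integer(),
                      signal_mean = numeric(), dapi_mean = numeric(),
                      dapi_integrated = numeric())
  if (length(nz) == 0) return(empty)
  lab <- labels[nz]
  ids <- sort(unique(lab))
  g <- factor(lab, levels = ids)
  rows <- (nz - 1L) %% nrow(labels) + 1L
  cols <- (nz - 1L) %/% nrow(labels) + 1L
  area <- as.integer(table(g))
  dapi_sum <- as.numeric(tapply(as.numeric(dapi_image[nz]), g, sum))
  data.frame(nucleus_id = ids,
             centroid_row = as.numeric(tapply(rows, g, mean)),
             centroid_col = as.numeric(tapply(cols, g, mean)),
             area = area,
             signal_mean = as.numeric(tapply(as.numeric(signal_image[nz]),
                                             g, mean)),
             dapi_mean = dapi_sum / area,
             dapi_integrated = dapi_sum)
}
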