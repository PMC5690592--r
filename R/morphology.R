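# Binary morphology on H x W masks. Closing/opening use the 3x3 cross
# (4-connected) structuring element throughout, via EBImage; connected
# component labelling is 4-connected.

struct_cross <- function() matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L)

#' Morphological closing with a 3x3 cross
#' @param mask binary matrix.
#' @return logical matrix.
#' @export
mask_closing <- function(mask) {
  EBImage::closing(mask * 1, struct_cross()) > 0.5
}

#' Morphological opening with a 3x3 cross
#' @param mask binary matrix.
#' @return logical matrix.
#' @export
mask_opening <- function(mask) {
  EBImage::opening(mask * 1, struct_cross()) > 0.5
}

mask_dilate <- function(mask) {
  EBImage::dilate(mask * 1, struct_cross()) > 0.5
}

#' Label 4-connected components of a binary mask
#'
#' @param mask binary matrix.
#' @return integer matrix of the same size; 0 for background, components
#'   numbered from 1 in discovery (column-major) order.
#' @export
label_components4 <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (px - 1L) %% h + 1L
      cl <- (px - 1L) %/% h + 1L
      for (nb in c(if (r > 1L) px - 1L, if (r < h) px + 1L,
                   if (cl > 1L) px - h, if (cl < w) px + h)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# Keep only the largest 4-connected component (first on ties); empty in,
# empty out.
largest_component4 <- function(mask) {
  lab <- label_components4(mask)
  if (max(lab) <= 1L) return(mask != 0)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
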