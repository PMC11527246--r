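#' Built-in spinal electrode-grid montages
#'
#' Returns the geometry of the 17-electrode spinal grid used for cervical and
#' lumbar electrospinography. The grid is centred on an anatomical target
#' electrode (over the spinous process of the sixth cervical vertebra for the
#' cervical grid, the first lumbar vertebra for the lumbar grid) and consists
#' of a vertical midline column of five electrodes with 2 cm spacing (the
#' third being the target), columns of four electrodes 1 cm to each side, and
#' columns of two electrodes 5 cm to each side. Coordinates are flat patch
#' coordinates in cm, x positive to the right, y positive rostral, origin at
#' the target electrode.
#'
#' @param name `"cervical"` or `"lumbar"`.
#' @return a `montage_spec`: list with `name`, `electrodes` (data.frame with
#'   `label`, `patch`, `x_cm`, `y_cm`), `target_label`, and `reference_label`
#'   (the common thoracic recording reference).
#' @export
#' @examples
#' m <- builtin_montage("cervical")
#' nrow(m$electrodes)  # 17
builtin_montage <- function(name = c("cervical", "lumbar")) {
  name <- match.arg(name)
  target <- if (name == "cervical") "SC6" else "L1"
  pre <- if (name == "cervical") "C" else "L"
  x <- c(rep(0, 5), rep(-1, 4), rep(1, 4), rep(-5, 2), rep(5, 2))
  y <- c(seq(4, -4, by = -2),          # midline: 5 at 2 cm spacing
         seq(3, -3, by = -2),          # inner left: 4
         seq(3, -3, by = -2),          # inner right: 4
         c(1, -1), c(1, -1))           # outer columns: 2 each side
  lab <- paste0(pre, "G", seq_along(x))
  lab[x == 0 & y == 0] <- target
  electrodes <- data.frame(label = lab, patch = name, x_cm = x, y_cm = y,
                           stringsAsFactors = FALSE)
  structure(list(name = name, electrodes = electrodes,
                 target_label = target, reference_label = "TH6"),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", x$name, ": ", nrow(x$electrodes),
      " electrodes, target ", x$target_label, ", reference ",
      x$reference_label, "\n", sep = "")
  invisible(x)
}

#' Read / write a montage specification as TSV
#'
#' The on-disk form is a plain tab-separated table with columns
#' `label`, `patch`, `x_cm`, `y_cm`.
#'
#' @param montage a `montage_spec`.
#' @param path file path.
#' @return `read_montage` returns a `montage_spec`; the target is taken to be
#'   the electrode at the origin and the reference defaults to TH6.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage$electrodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "patch", "x_cm", "y_cm") %in% names(el)))
  at0 <- which(el$x_cm == 0 & el$y_cm == 0)
  structure(list(name = el$patch[1], electrodes = el,
                 target_label = if (length(at0)) el$label[at0[1]] else NA,
                 reference_label = "TH6"),
            class = "montage_spec")
}

#' Channel-adjacency graph of a grid montage
#'
#' Two grid electrodes are neighbours when their Euclidean distance does not
#' exceed `max_dist_cm`. The default of 2.5 cm links the 1 cm and 2 cm
#' neighbours of the dense part of the grid but leaves the 5 cm outer columns
#' attached only through nothing closer, so the graph should be checked for
#' connectedness when the outer columns are included in an analysis.
#'
#' @param montage a `montage_spec`, or a data.frame with `x_cm`, `y_cm`.
#' @param max_dist_cm neighbour distance cutoff in cm.
#' @return a logical adjacency matrix (labels as dimnames, diagonal FALSE).
#' @export
montage_adjacency <- function(montage, max_dist_cm = 2.5) {
  el <- if (inherits(montage, "montage_spec")) montage$electrodes else montage
  d <- as.matrix(stats::dist(el[, c("x_cm", "y_cm")]))
  adj <- d > 0 & d <= max_dist_cm
  dimnames(adj) <- list(el$label, el$label)
  adj
}
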