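# Master-window and sub-window enumeration over the GO-BP gene order.
# All window arithmetic is on gene ranks (positions in the per-chromosome
# order of GO-BP-annotated genes), never on base pairs.

# Fixed default sub-window tiling for a 24-gene master window: one window
# per length 24 and 18/12/8/6 at systematic offsets, 13 sub-windows in
# total including the master itself, spanning lengths 6..24.
.default_entries <- list(
  list(length = 24L, offsets = 0L),
  list(length = 18L, offsets = c(0L, 6L)),
  list(length = 12L, offsets = c(0L, 6L, 12L)),
  list(length = 8L,  offsets = c(0L, 8L, 16L)),
  list(length = 6L,  offsets = c(0L, 6L, 12L, 18L))
)

#' Sub-window scheme
#'
#' The discrete set of (offset, length) sub-windows probed inside each
#' master window. The default scheme for a full 24-gene master yields 13
#' sub-windows (lengths 24, 18, 12, 8, 6 at systematic offsets, the master
#' itself included); exhaustive mode probes every contiguous sub-window of
#' at least `min_length` genes (253 for a 24-gene master at
#' `min_length = 3`).
#'
#' @param mode `"default"` or `"exhaustive"`.
#' @param min_length Shortest sub-window; defaults to 6 in default mode
#'   and 3 in exhaustive mode.
#' @param entries Default-mode tiling as a list of
#'   `list(length =, offsets =)` records; override to probe a custom set.
#' @return An object of class `SubWindowScheme`.
#' @export
subwindow_scheme <- function(mode = c("default", "exhaustive"),
                             min_length = NULL, entries = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_length)) min_length <- if (mode == "default") 6L else 3L
  if (mode == "default" && is.null(entries)) entries <- .default_entries
  structure(list(mode = mode, min_length = as.integer(min_length),
                 entries = entries), class = "SubWindowScheme")
}

#' Enumerate master windows over the GO-BP gene order
#'
#' Tiles each chromosome's ordered GO-BP-annotated genes into consecutive,
#' non-overlapping blocks of `master_size` genes. A trailing block shorter
#' than `master_size` is kept if it holds at least `min_trailing` genes
#' (the shortest testable sub-window); smaller remainders are dropped.
#'
#' @param catalog A `GeneCatalog`.
#' @param master_size Genes per master window (default 24).
#' @param min_trailing Minimum size of a kept trailing window (default 6).
#' @return List of master windows, each a list with `chromosome`,
#'   `bp_start_rank`, `bp_end_rank` (0-based half-open ranks into the
#'   chromosome's GO-BP order) and `size`.
#' @export
enumerate_master_windows <- function(catalog, master_size = 24L,
                                     min_trailing = 6L) {
  if (master_size < min_trailing)
    stop("master_size must be at least ", min_trailing)
  out <- list()
  for (ch in names(catalog$bp_order)) {
    n <- length(catalog$bp_order[[ch]])
    if (n < min_trailing) next
    starts <- seq(0L, n - 1L, by = master_size)
    for (s in starts) {
      size <- min(master_size, n - s)
      if (size < min_trailing) next
      out[[length(out) + 1L]] <- list(
        chromosome = ch, bp_start_rank = as.integer(s),
        bp_end_rank = as.integer(s + size), size = as.integer(size))
    }
  }
  out
}

#' Enumerate the sub-windows probed inside a master window
#'
#' In default mode the fixed scheme is clipped to the master size
#' (sub-windows that would overrun a short trailing master are skipped)
#' and the master window itself is always included as a sub-window. In
#' exhaustive mode every (offset, length) with
#' `min_length <= length <= master size` is emitted. Order is
#' deterministic: length descending, offset ascending.
#'
#' @param master A master window from [enumerate_master_windows()], or an
#'   integer master size.
#' @param scheme A [subwindow_scheme()].
#' @return Data frame with columns `offset`, `length`.
#' @export
enumerate_sub_windows <- function(master, scheme = subwindow_scheme()) {
  size <- if (is.list(master)) master$size else as.integer(master)
  if (scheme$mode == "exhaustive") {
    lens <- seq(min(size, scheme$min_length), size)
    out <- do.call(rbind, lapply(rev(lens), function(l)
      data.frame(offset = 0:(size - l), length = l)))
  } else {
    rows <- lapply(scheme$entries, function(e) {
      off <- e$offsets[e$offsets + e$length <= size]
      if (!length(off) || e$length > size) return(NULL)
      data.frame(offset = as.integer(off), length = as.integer(e$length))
    })
    out <- do.call(rbind, c(list(data.frame(offset = 0L, length = size)),
                            rows))
    out <- out[!duplicated(out), , drop = FALSE]
    out <- out[order(-out$length, out$offset), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
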