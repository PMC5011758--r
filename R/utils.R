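# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_pos <- function(x, name) {
  if (!is_num1(x) || x <= 0) stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

# Runs of TRUE values in a logical vector; data.frame with integer
# columns start, end (inclusive).
#' @noRd
true_runs <- function(v) {
  v <- as.logical(v)
  v[is.na(v)] <- FALSE
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Close gaps of at most `gap` FALSE entries between TRUE runs.
#' @noRd
close_gaps <- function(v, gap) {
  if (gap < 1L) return(v)
  r <- rle(as.logical(v))
  n <- length(r$lengths)
  if (n >= 3L) {
    for (i in seq(2L, n - 1L)) {
      if (!r$values[i] && r$lengths[i] <= gap && r$values[i - 1L] && r$values[i + 1L])
        r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Label connected components of a logical matrix
#'
#' 4-connectivity comes straight from [EBImage::bwlabel()]; 8-connectivity
#' additionally merges labels that touch diagonally with a small
#' union-find pass.  Cavity analysis uses 4-connectivity so that a
#' diagonal void-to-void contact through an intact one-pixel bone wall
#' does not merge two holes.
#'
#' @param px Logical matrix (`TRUE` = foreground).
#' @param connectivity 4 or 8.
#' @return Integer label matrix, 0 for background.
#' @export
label_components <- function(px, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(px), nrow = nrow(px))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(m))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left diagonal
    p <- rbind(
      cbind(as.vector(a1), as.vector(b1)),
      cbind(as.vector(a2), as.vector(b2))
    )
    p <- p[p[, 1L] > 0L & p[, 2L] > 0L & p[, 1L] != p[, 2L], , drop = FALSE]
    if (nrow(p)) {
      p <- unique(p)
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(p))) {
        ra <- find(p[k, 1L]); rb <- find(p[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), find, integer(1))
      ids <- match(roots, sort(unique(roots)))
      nz <- lab > 0L
      lab[nz] <- ids[lab[nz]]
    }
  }
  lab
}

# Evaluate code with a temporary RNG state restored on exit.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Merge numeric intervals (2-col matrix) into disjoint intervals.
#' @noRd
merge_intervals <- function(iv, tol = 0) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in seq(2L, nrow(iv))) {
      j <- nrow(out)
      if (iv[i, 1L] <= out[j, 2L] + tol) {
        out[j, 2L] <- max(out[j, 2L], iv[i, 2L])
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
  }
  out
}
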