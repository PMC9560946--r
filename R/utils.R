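#' @importFrom methods is
#' @importFrom stats rbinom rlnorm rpois runif setNames
#' @importFrom utils read.table write.table
NULL

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Half-up rounding at `digits` decimals; base round() is half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- interval sets -------------------------------------------------------
#
# Intervals travel as data.frames (contig, start, end), 0-based half-open —
# the BED convention. GRanges (1-based closed) is used internally for merge
# and overlap arithmetic; conversion happens only at these two helpers.

#' Build a normalized interval set
#'
#' Normalizes (sorts and merges) a set of genomic intervals in BED
#' convention: 0-based, half-open `[start, end)`.
#'
#' @param contig character vector of contig ids.
#' @param start,end integer vectors, 0-based half-open.
#' @return A `data.frame` with columns `contig`, `start`, `end`, sorted by
#'   (contig, start), with overlapping or adjacent intervals merged.
#' @examples
#' interval_set(c("c1", "c1"), c(0, 5), c(10, 20))  # merges to [0, 20)
#' @export
interval_set <- function(contig = character(), start = integer(),
                         end = integer()) {
  if (length(contig) == 1L && length(start) > 1L) {
    contig <- rep(contig, length(start))
  }
  if (length(contig) != length(start) || length(start) != length(end)) {
    stop_invalid("interval_set: contig/start/end lengths differ")
  }
  if (length(contig) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(end <= start)) {
    stop_invalid("interval_set: end <= start at entry %d",
                 which(end <= start)[1L])
  }
  if (any(start < 0)) stop_invalid("interval_set: negative start")
  gr <- GenomicRanges::reduce(intervals_to_gr(
    data.frame(contig = as.character(contig), start = start, end = end)))
  gr_to_intervals(gr)
}

intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_intervals <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

interval_total_length <- function(df) {
  if (nrow(df) == 0L) return(0)
  merged <- interval_set(df$contig, df$start, df$end)
  sum(merged$end - merged$start)
}

# Membership of 1-based positions in a 0-based half-open interval set.
positions_in_intervals <- function(contig, pos, intervals) {
  if (length(pos) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1))
  # seqlevels are plain labels here; a contig absent from one side is fine
  suppressWarnings(IRanges::overlapsAny(q, intervals_to_gr(intervals)))
}
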