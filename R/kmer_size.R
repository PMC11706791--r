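#' Count canonical k-mers in a set of reads
#'
#' Plain (exact, hash-free) canonical k-mer counting: each window of length
#' `k` is encoded as a base-4 integer together with its reverse complement,
#' and the lexicographically smaller of the two is kept. Windows containing
#' a non-ACGT character are skipped. `k` must be odd so that no k-mer is
#' its own reverse complement (canonical ambiguity).
#'
#' Codes fit exactly in doubles for `k <= 26` (< 2^53), which covers the
#' usual 15-31 range used for genome-size estimation up to k = 25.
#'
#' @param reads Character vector of reads, a [Biostrings::DNAStringSet], or
#'   a path to a FASTA/FASTQ file (format sniffed from the first byte).
#' @param k Odd word size, `15 <= k <= 25` typical; `k <= 26` required.
#' @return Object of class `KmerHistogram`: list with `k`, `counts`
#'   (named vector: multiplicity -> number of distinct k-mers),
#'   `total_kmers` (sum of multiplicity * count = valid windows).
#' @export
count_kmers <- function(reads, k) {
  if (k %% 2 == 0) stopf("k must be odd (canonical k-mers are ambiguous otherwise)")
  if (k > 26) stopf("k > 26 exceeds exact double precision for k-mer codes")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    first <- readChar(reads, 1)
    fmt <- if (first == "@") "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)

  # concatenate reads with an N separator: windows crossing a read boundary
  # contain the N and are dropped automatically
  seq <- paste(reads, collapse = "N")
  lut <- rep(NA_real_, 256)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("T")] <- 3
  b <- lut[utf8ToInt(seq)]
  n <- length(b)
  if (n < k) {
    h <- structure(list(k = k, counts = stats::setNames(numeric(0),
                                                        character(0)),
                        total_kmers = 0), class = "KmerHistogram")
    return(h)
  }
  nwin <- n - k + 1
  code <- numeric(nwin)
  rccode <- numeric(nwin)
  for (j in 0:(k - 1)) {
    seg <- b[(1 + j):(nwin + j)]
    code <- code + seg * 4^(k - 1 - j)     # forward, base-4 big-endian
    rccode <- rccode + (3 - seg) * 4^j     # reverse complement
  }
  canon <- pmin(code, rccode)
  canon <- canon[!is.na(canon)]
  if (!length(canon)) {
    return(structure(list(k = k,
                          counts = stats::setNames(numeric(0), character(0)),
                          total_kmers = 0), class = "KmerHistogram"))
  }
  r <- rle(sort(canon))
  mult <- tabulate(r$lengths)
  names(mult) <- seq_along(mult)
  mult <- mult[mult > 0]
  structure(list(k = k, counts = mult, total_kmers = length(canon)),
            class = "KmerHistogram")
}

#' @export
print.KmerHistogram <- function(x, ...) {
  cat(sprintf("KmerHistogram: k = %d, %d distinct multiplicities, %.3g k-mer instances\n",
              x$k, length(x$counts), x$total_kmers))
  invisible(x)
}

#' Coverage-peak genome-size estimate from a k-mer histogram
#'
#' Simple peak estimator: the low-multiplicity error tail is separated from
#' the coverage peak at the first local minimum of the 3-point moving
#' average of the histogram; the coverage peak is the modal multiplicity
#' above that cutoff, refined by 3-point parabolic interpolation plus a
#' half-multiplicity continuity correction (the parabola vertex of a
#' Poisson-like coverage histogram sits half a bin below the mean
#' coverage), for
#' sub-integer precision; and
#' `estimated size = sum(multiplicity * count | multiplicity >= cutoff) / peak`.
#' With error-free reads the error tail is empty and the cutoff sits at the
#' left edge of the histogram.
#'
#' @param histogram A `KmerHistogram` from [count_kmers()].
#' @return List: `est_size` (bp), `error_cutoff`, `peak` (refined),
#'   `peak_mode` (integer mode).
#' @export
estimate_genome_size <- function(histogram) {
  counts <- histogram$counts
  if (!length(counts)) stopf("empty k-mer histogram")
  maxm <- max(as.integer(names(counts)))
  c_full <- numeric(maxm)
  c_full[as.integer(names(counts))] <- counts
  # 3-point moving average (edges use the available neighbours)
  s <- vapply(seq_len(maxm), function(m)
    mean(c_full[max(1, m - 1):min(maxm, m + 1)]), numeric(1))

  # first local minimum of the smoothed histogram = error/coverage boundary;
  # if the histogram rises from the left (no error tail) the cutoff is 1
  cutoff <- NA_integer_
  if (maxm >= 3 && s[2] >= s[1]) {
    cutoff <- 1L
  } else {
    for (m in 2:(maxm - 1)) {
      if (s[m] <= s[m - 1] && s[m] <= s[m + 1]) { cutoff <- m; break }
    }
  }
  if (is.na(cutoff))
    stopf("no error/coverage separation in the k-mer histogram; increase coverage")
  region <- cutoff:maxm
  pk <- region[which.max(s[region])]
  if (pk <= cutoff && cutoff > 1)
    stopf("no coverage peak above the error cutoff; increase coverage")
  # parabolic refinement around the mode, plus half a bin: the vertex of a
  # Poisson(lambda) histogram lies near lambda - 1/2, and the estimator
  # wants the mean k-mer coverage lambda in the denominator
  peak <- pk
  if (pk > 1 && pk < maxm) {
    y0 <- s[pk - 1]; y1 <- s[pk]; y2 <- s[pk + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) peak <- pk + 0.5 * (y0 - y2) / denom + 0.5
  }
  mass <- sum(as.numeric(region) * c_full[region])
  list(est_size = mass / peak, error_cutoff = cutoff, peak = peak,
       peak_mode = pk)
}
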