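# core_io: alignment reading/writing, character normalization, MAF
# projection, window partitioning and per-window analyzability.

# byte -> state lookup used throughout: A=0, C=1, G=2, T=3, missing=4
.state_lookup <- local({
  lut <- rep(4L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
})

#' Construct a GenomeAlignment
#'
#' @param seqs Named character vector or `DNAStringSet` of equal-length
#'   aligned sequences.
#' @return A [GenomeAlignment-class].
#' @export
GenomeAlignment <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  methods::validObject(obj <- methods::new("GenomeAlignment", seqs = seqs))
  obj
}

#' Taxa, length and sequence access for alignments
#'
#' `alnTaxa` returns the taxon labels, `alnLength` the number of sites and
#' `alnSequences` the underlying `DNAStringSet`.
#'
#' @param x A [GenomeAlignment-class].
#' @return Character vector, integer, or `DNAStringSet` respectively.
#' @export
alnTaxa <- function(x) names(x@seqs)

#' @rdname alnTaxa
#' @export
alnLength <- function(x) Biostrings::width(x@seqs)[1]

#' @rdname alnTaxa
#' @export
alnSequences <- function(x) x@seqs

# Normalize raw sequence text to the package alphabet: uppercase; U -> T;
# '?' and '.' -> '-'; any other non-ACGT, non-gap character -> N.
.normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- gsub("[?.]", "-", x)
  gsub("[^ACGT-]", "N", x)
}

#' Read a FASTA alignment
#'
#' Sequences are uppercased; `U` is mapped to `T`; `?` and `.` are mapped
#' to `-`; every other character outside `A,C,G,T,-` (including IUPAC
#' ambiguity codes) is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A [GenomeAlignment-class].
#' @export
readAlignmentFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  txt <- .normalize_seq(as.character(raw))
  # FASTA descriptions: taxon label is the first whitespace-delimited word
  names(txt) <- sub("\\s.*$", "", names(raw))
  if (length(unique(nchar(txt))) != 1L)
    stop("FASTA records have unequal lengths; not an alignment: ", path)
  GenomeAlignment(txt)
}

#' Write a GenomeAlignment to FASTA
#'
#' @param x A [GenomeAlignment-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeAlignmentFasta <- function(x, path) {
  Biostrings::writeXStringSet(x@seqs, filepath = path, width = 80L)
  invisible(path)
}

# Encode an alignment as an integer matrix (taxa x sites, states 0..4).
# The row order follows alnTaxa(x) unless `taxa` reorders/subsets it.
.encode_alignment <- function(x, taxa = NULL) {
  seqs <- x@seqs
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, names(seqs))
    if (length(miss))
      stop("taxa not in alignment: ", paste(miss, collapse = ", "))
    seqs <- seqs[taxa]
  }
  L <- Biostrings::width(seqs)[1]
  enc <- matrix(0L, nrow = length(seqs), ncol = L)
  chr <- as.character(seqs)
  for (i in seq_along(seqs)) {
    enc[i, ] <- .state_lookup[as.integer(charToRaw(chr[[i]])) + 1L]
  }
  rownames(enc) <- names(seqs)
  enc
}

# Decode an integer matrix of states 0..4 back to a GenomeAlignment.
.decode_alignment <- function(enc) {
  bytes <- as.raw(c(65L, 67L, 71L, 84L, 45L))  # A C G T -
  txt <- vapply(seq_len(nrow(enc)),
                function(i) rawToChar(bytes[enc[i, ] + 1L]), character(1))
  names(txt) <- rownames(enc)
  GenomeAlignment(txt)
}

#' Extract a window of an alignment
#'
#' @param x A [GenomeAlignment-class].
#' @param start,end 0-based half-open site interval.
#' @return A [GenomeAlignment-class] of `end - start` sites.
#' @export
alnWindow <- function(x, start, end) {
  if (start < 0 || end > alnLength(x) || end <= start)
    stop("invalid window [", start, ", ", end, ")")
  GenomeAlignment(Biostrings::subseq(x@seqs, start = start + 1L, end = end))
}

# ------------------------------------------------------------------ MAF

#' Project a MAF file onto a reference taxon as a single FASTA alignment
#'
#' Reads MAF alignment blocks, restricts them to `keep`, drops every column
#' in which the reference taxon has a gap, fills taxa absent from a block
#' with `-`, and concatenates the blocks in order of reference coordinate.
#' Blocks missing the reference taxon are skipped with a warning.  Source
#' names of the form `taxon.chrom` are shortened to `taxon`.
#'
#' @param path Path to an (uncompressed) MAF file.
#' @param reference Reference taxon label.
#' @param keep Character vector of taxa to retain; must include
#'   `reference`.
#' @return A [GenomeAlignment-class] whose length equals the number of
#'   reference non-gap columns across retained blocks.
#' @export
projectMafToReference <- function(path, reference, keep) {
  if (!reference %in% keep) stop("`keep` must include the reference taxon")
  lines <- readLines(path)
  starts <- grep("^a", lines)
  if (length(starts) == 0L) stop("no alignment blocks in MAF file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  blocks <- vector("list", length(starts))
  refstart <- numeric(length(starts))
  nskip <- 0L
  for (b in seq_along(starts)) {
    chunk <- lines[seq(bounds[b] + 1L, bounds[b + 1L] - 1L)]
    schunk <- chunk[startsWith(chunk, "s ")]
    if (length(schunk) == 0L) next
    fields <- strsplit(trimws(schunk), "\\s+")
    src <- vapply(fields, `[`, character(1), 2L)
    taxa <- sub("\\..*$", "", src)
    text <- toupper(vapply(fields, `[`, character(1), 7L))
    ok <- taxa %in% keep
    taxa <- taxa[ok]; text <- text[ok]
    fields <- fields[ok]
    if (!reference %in% taxa) {
      nskip <- nskip + 1L
      next
    }
    ri <- match(reference, taxa)
    refstart[b] <- as.numeric(fields[[ri]][3L])
    refchars <- strsplit(text[ri], "")[[1]]
    keepcol <- refchars != "-"
    mat <- matrix("-", nrow = length(keep), ncol = sum(keepcol),
                  dimnames = list(keep, NULL))
    for (i in seq_along(taxa)) {
      ch <- strsplit(text[i], "")[[1]][keepcol]
      mat[taxa[i], ] <- ch
    }
    blocks[[b]] <- mat
  }
  if (nskip > 0L)
    warning(nskip, " MAF block(s) skipped: reference taxon absent")
  used <- !vapply(blocks, is.null, logical(1))
  if (!any(used)) stop("no MAF block contained the reference taxon")
  ord <- order(refstart[used])
  mat <- do.call(cbind, blocks[used][ord])
  txt <- .normalize_seq(apply(mat, 1L, paste0, collapse = ""))
  names(txt) <- keep
  GenomeAlignment(txt)
}

# ------------------------------------------------------------------ windows

#' Partition an alignment into non-overlapping windows
#'
#' Produces `floor(alignmentLength / windowSize)` contiguous windows of
#' exactly `windowSize` sites starting at position 0.  The trailing
#' remainder (`alignmentLength %% windowSize` sites) is excluded from all
#' windowed analyses.  Analyzability flags start out all `TRUE`; apply
#' [windowAnalyzable()] to set them.
#'
#' @param alignmentLength Total sites in the alignment.
#' @param windowSize Sites per window; must satisfy
#'   `1 <= windowSize <= alignmentLength`.
#' @return A [WindowPartition-class].
#' @export
makeWindows <- function(alignmentLength, windowSize) {
  if (windowSize <= 0) stop("windowSize must be positive")
  if (windowSize > alignmentLength)
    stop("windowSize exceeds alignment length")
  n <- floor(alignmentLength / windowSize)
  iv <- IRanges::IRanges(start = (seq_len(n) - 1L) * windowSize + 1L,
                         width = windowSize)
  methods::new("WindowPartition", windowSize = as.integer(windowSize),
               intervals = iv, analyzable = rep(TRUE, n))
}

#' Window starts/ends in 0-based half-open coordinates
#'
#' @param partition A [WindowPartition-class].
#' @return `windowStarts`/`windowEnds`: integer vectors;
#'   `nWindows`: window count.
#' @export
windowStarts <- function(partition) IRanges::start(partition@intervals) - 1L

#' @rdname windowStarts
#' @export
windowEnds <- function(partition) IRanges::end(partition@intervals)

#' @rdname windowStarts
#' @export
nWindows <- function(partition) length(partition@intervals)

#' Decide whether a window alignment can be analyzed
#'
#' In strict mode (the default) a window is analyzable only if every taxon
#' has at least one non-gap, non-N character.  In lenient mode a window is
#' analyzable when at least `minTaxaWithData` taxa have data (the
#' "fewer than three species contain data" rule; taxa without data are
#' then dropped from that window's fit).
#'
#' @param x A [GenomeAlignment-class] (typically one window).
#' @param minTaxaWithData Minimum number of data-bearing taxa (lenient
#'   mode); default 3.
#' @param strict If `TRUE`, additionally require every taxon to have data.
#' @return Logical scalar.
#' @export
isAnalyzable <- function(x, minTaxaWithData = 3L, strict = TRUE) {
  enc <- .encode_alignment(x)
  has <- rowSums(enc != 4L) > 0L
  if (strict) all(has) else sum(has) >= minTaxaWithData
}

#' Flag analyzable windows of a partition
#'
#' Vectorized version of [isAnalyzable()] over all windows of a partition.
#'
#' @param x A [GenomeAlignment-class] or an encoded matrix from it.
#' @param partition A [WindowPartition-class].
#' @inheritParams isAnalyzable
#' @return The partition with its `analyzable` slot filled in.
#' @export
windowAnalyzable <- function(x, partition, minTaxaWithData = 3L,
                             strict = TRUE) {
  enc <- if (is.matrix(x)) x else .encode_alignment(x)
  st <- windowStarts(partition)
  en <- windowEnds(partition)
  ntax <- nrow(enc)
  nw <- length(st)
  hasdata <- matrix(FALSE, nrow = ntax, ncol = nw)
  for (i in seq_len(ntax)) {
    cs <- c(0L, cumsum(enc[i, ] != 4L))
    hasdata[i, ] <- (cs[en + 1L] - cs[st + 1L]) > 0L
  }
  counts <- colSums(hasdata)
  partition@analyzable <- if (strict) counts == ntax
                          else counts >= minTaxaWithData
  partition
}

#' Write a window partition as a BED-like audit table
#'
#' Tab-separated columns: chrom, 0-based start, end, 1-based window index,
#' analyzable flag.
#'
#' @param partition A [WindowPartition-class].
#' @param path Output path.
#' @param chrom Chromosome label for the first column.
#' @return Invisibly, the data.frame written.
#' @export
writeWindowBed <- function(partition, path, chrom = "chr") {
  df <- data.frame(chrom = chrom, start = windowStarts(partition),
                   end = windowEnds(partition),
                   window_index = seq_len(nWindows(partition)),
                   analyzable = partition@analyzable)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
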