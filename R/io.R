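#' @importFrom data.table fread fwrite
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width
#'   strand strand<- reduce gaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## field-count check shared by the BED-family readers; errors name the first
## offending line so malformed input is actionable
.checkFields <- function(path, minFields, what) {
    nf <- utils::count.fields(path, sep = "\t", quote = "",
                              comment.char = "")
    if (is.null(nf)) return(invisible(0L))  # empty file
    bad <- which(nf < minFields)
    if (length(bad))
        stop(sprintf("%s: line %d of '%s' has %d field(s); %d required",
                     what, bad[1L], path, nf[bad[1L]], minFields),
             call. = FALSE)
    invisible(length(nf))
}

#' Read strand-annotated aligned reads from a BED6 file
#'
#' Parses a BED file with at least six columns into a \code{GRanges} of
#' aligned reads. BED coordinates are 0-based half-open; the returned
#' \code{GRanges} uses the usual 1-based inclusive convention, so a BED record
#' \code{start=100, end=135} becomes \code{[101, 135]}. Every read must carry
#' a strand of \code{+} or \code{-}; records with \code{.} strand are
#' rejected, since the shape model needs strand-resolved counts.
#'
#' @param path path to a BED6 (or wider) file of aligned reads.
#' @return a \code{GRanges} with one range per read, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t135\tr1\t0\t+", bed)
#' readBedReads(bed)
#' @export
readBedReads <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    n <- .checkFields(path, 6L, "BED6 reads")
    if (n == 0L)
        return(GRanges())
    bed <- fread(path, header = FALSE, sep = "\t", quote = "",
                 select = 1:6,
                 col.names = c("chrom", "start", "end", "name", "score",
                               "strand"),
                 colClasses = list(character = c(1L, 4L, 6L)))
    if (!is.numeric(bed$start) || !is.numeric(bed$end))
        stop("BED6 reads: non-numeric coordinates in '", path, "'",
             call. = FALSE)
    badStrand <- which(!(bed$strand %in% c("+", "-")))
    if (length(badStrand))
        stop(sprintf(
            "BED6 reads: line %d of '%s' has strand '%s'; must be '+' or '-'",
            badStrand[1L], path, bed$strand[badStrand[1L]]), call. = FALSE)
    badCoord <- which(bed$start >= bed$end | bed$start < 0)
    if (length(badCoord))
        stop(sprintf("BED6 reads: line %d of '%s' has start >= end",
                     badCoord[1L], path), call. = FALSE)
    GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end),
            strand = bed$strand)
}

#' Read a candidate peak list with summits
#'
#' Supports the ENCODE narrowPeak format (BED6+4; column 10 is the summit
#' offset from the peak start, or -1 when no summit was called) and plain
#' summit-BED (the interval midpoint is used as the summit). Source ranks are
#' assigned by decreasing signal (narrowPeak column 7), with ties broken by
#' file order; for summit-BED the file order is the rank.
#'
#' @param path path to the peak file.
#' @param format \code{"narrowPeak"} or \code{"summitBed"}.
#' @return a \code{GRanges} with metadata columns \code{summit} (absolute
#'   1-based position), \code{sourceRank} (1 = best), \code{sourceScore} and
#'   \code{id} (unique).
#' @export
readPeaks <- function(path, format = c("narrowPeak", "summitBed")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    minFields <- if (format == "narrowPeak") 10L else 3L
    n <- .checkFields(path, minFields, format)
    if (n == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(summit = integer(), sourceRank = integer(),
                               sourceScore = numeric(), id = character())
        return(gr)
    }
    tab <- fread(path, header = FALSE, sep = "\t", quote = "",
                 colClasses = list(character = 1L))
    chrom <- as.character(tab[[1L]])
    start0 <- as.numeric(tab[[2L]])
    end0 <- as.numeric(tab[[3L]])
    if (any(start0 >= end0))
        stop(format, ": start >= end at line ",
             which(start0 >= end0)[1L], call. = FALSE)
    if (format == "narrowPeak") {
        offset <- as.numeric(tab[[10L]])
        summit0 <- ifelse(offset >= 0, start0 + offset,
                          floor((start0 + end0) / 2))
        score <- as.numeric(tab[[7L]])
        sourceRank <- integer(length(score))
        sourceRank[order(-score)] <- seq_along(score)  # stable: file order
    } else {
        summit0 <- floor((start0 + end0) / 2)
        score <- rep(NA_real_, length(start0))
        sourceRank <- seq_along(start0)
    }
    bad <- which(summit0 < start0 | summit0 >= end0)
    if (length(bad))
        stop(sprintf("%s: line %d summit %d outside [%d, %d)",
                     format, bad[1L], summit0[bad[1L]], start0[bad[1L]],
                     end0[bad[1L]]), call. = FALSE)
    id <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else NA_character_
    if (anyNA(id) || anyDuplicated(id) || any(id == "."))
        id <- sprintf("peak_%d", seq_along(chrom))
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    mcols(gr) <- DataFrame(summit = as.integer(summit0 + 1L),
                           sourceRank = sourceRank,
                           sourceScore = score, id = id)
    gr
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp (the layout of
#' a UCSC chrom.sizes file or the first two columns of a samtools faidx
#' index).
#'
#' @param path path to the table.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    .checkFields(path, 2L, "chrom sizes")
    tab <- fread(path, header = FALSE, sep = "\t",
                 colClasses = list(character = 1L))
    len <- as.numeric(tab[[2L]])
    if (any(!is.finite(len) | len <= 0))
        stop("chrom sizes: non-positive length", call. = FALSE)
    stats::setNames(len, as.character(tab[[1L]]))
}

#' Write a ranked peak table
#'
#' Writes the output of [rankPeaks()] as a tab-delimited table with header
#' \code{chrom, start, end, summit, id, source_rank, posterior, logLR,
#' total_count, new_rank}. Coordinates are written back in BED convention
#' (0-based half-open starts, absolute 0-based summit). Floating-point
#' columns are written with 12 significant digits so the table round-trips.
#'
#' @param ranked a ranked \code{GRanges} from [rankPeaks()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeRankedTable <- function(ranked, path) {
    mc <- mcols(ranked)
    need <- c("summit", "id", "sourceRank", "posterior", "logLR",
              "totalCount", "newRank")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        stop("ranked peaks lack column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    num12 <- function(x) sprintf("%.12g", x)
    out <- data.frame(
        chrom = as.character(seqnames(ranked)),
        start = start(ranked) - 1L,
        end = end(ranked),
        summit = mc$summit - 1L,
        id = mc$id,
        source_rank = mc$sourceRank,
        posterior = num12(mc$posterior),
        logLR = num12(mc$logLR),
        total_count = mc$totalCount,
        new_rank = mc$newRank,
        check.names = FALSE, stringsAsFactors = FALSE)
    fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read back a ranked peak table
#'
#' Inverse of [writeRankedTable()]; used for round-tripping and downstream
#' evaluation.
#'
#' @param path path written by [writeRankedTable()].
#' @return a \code{data.frame} with the table's columns.
#' @export
readRankedTable <- function(path) {
    as.data.frame(fread(path, header = TRUE, sep = "\t",
                        colClasses = list(character = c("chrom", "id"))))
}

#' Write aligned reads as BED6
#'
#' @param reads a \code{GRanges} of reads with strand.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBedReads <- function(reads, path) {
    n <- length(reads)
    out <- data.frame(
        chrom = as.character(seqnames(reads)),
        start = start(reads) - 1L,
        end = end(reads),
        name = if (n) sprintf("read_%d", seq_len(n)) else character(),
        score = rep(0L, n),
        strand = as.character(strand(reads)),
        stringsAsFactors = FALSE)
    fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write candidate peaks in narrowPeak format
#'
#' @param peaks a \code{GRanges} with \code{summit}, \code{sourceScore} and
#'   \code{id} metadata (as from [readPeaks()] or the simulator).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNarrowPeak <- function(peaks, path) {
    mc <- mcols(peaks)
    out <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L,
        end = end(peaks),
        name = mc$id,
        score = 0L,
        strand = ".",
        signalValue = mc$sourceScore,
        pValue = -1,
        qValue = -1,
        peak = mc$summit - start(peaks),  # offset from 0-based start
        stringsAsFactors = FALSE)
    fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
    invisible(path)
}
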