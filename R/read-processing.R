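#' @include AllClasses.R utils.R
NULL

#' Read a FASTQ file into a data.frame of records
#'
#' Thin wrapper over \link[Biostrings]{readQualityScaledDNAStringSet};
#' malformed input is reported with the file name.
#'
#' @param path FASTQ file (Sanger/Phred+33)
#' @return data.frame with columns id, seq, qual
#' @export
readFastqRecords <- function(path) {
    ## suppressWarnings: the reader warns about dropping its own internal
    ## metadata column when wrapping qualities; parse failures are errors
    x <- tryCatch(
        suppressWarnings(readQualityScaledDNAStringSet(path)),
        error = function(e) stop("malformed FASTQ in '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    data.frame(id = names(x), seq = as.character(x),
               qual = as.character(x@quality),
               stringsAsFactors = FALSE)
}

## first position (1-based) at which the 8-nt seed of the adapter matches
## with <= 1 mismatch, scanning starts 1..max_start; NA if none
.findAdapter3 <- function(seqs, adapter3, max_start) {
    seed <- substr(adapter3, 1, 8)
    hit <- rep(NA_integer_, length(seqs))
    for (s in seq_len(max_start)) {
        todo <- is.na(hit)
        if (!any(todo)) break
        mm <- .prefixMismatches(seqs[todo], seed, from = s)
        found <- !is.na(mm) & mm <= 1L
        hit[todo][found] <- s
    }
    hit
}

#' Clean raw small RNA reads and account for every removal category
#'
#' Reads failing the high-quality filter (more than \code{max_n_frac} N
#' bases or mean Phred quality below \code{min_mean_q}) are dropped first.
#' Each remaining read is assigned to exactly one category, tested in
#' fixed order: \code{adapter3_null} (no 3' adapter seed found with <= 1
#' mismatch in its first 8 nt, scanning insert starts up to
#' \code{max_len + 1}), \code{insert_null} (adapter at position 1),
#' \code{adapter5_contam} (trimmed insert begins with the 5' adapter seed,
#' <= 1 mismatch), \code{polyA} (insert at least \code{polyA_threshold}
#' adenine), \code{short_lt18} (insert shorter than \code{min_len}), and
#' \code{clean}.
#'
#' @param reads data.frame (id, seq, qual) from \code{readFastqRecords}
#'   or \code{\link{generateReads}}, or a FASTQ path
#' @param adapter3,adapter5 adapter sequences
#' @param min_len,max_len clean insert length bounds (default 18-30)
#' @param polyA_threshold adenine fraction defining a polyA insert
#' @param min_mean_q,max_n_frac high-quality filter thresholds
#' @return list with \code{clean} (\link[Biostrings]{DNAStringSet} of
#'   trimmed inserts), \code{report} (\linkS4class{CleaningReport}) and
#'   \code{assignments} (data.frame: id, category; high-quality reads only)
#' @export
cleanReads <- function(reads, adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       min_len = 18L, max_len = 30L,
                       polyA_threshold = 0.9,
                       min_mean_q = 20, max_n_frac = 0.1) {
    if (is.character(reads) && length(reads) == 1L)
        reads <- readFastqRecords(reads)
    stopifnot(is.data.frame(reads),
              all(c("id", "seq", "qual") %in% colnames(reads)))
    if (min_len < 1) stop("min_len must be >= 1")
    adapter3 <- .toDna(adapter3); adapter5 <- .toDna(adapter5)
    if (!nzchar(adapter3) || !nzchar(adapter5))
        stop("adapters must be non-empty")
    seqs <- .toDna(reads$seq)
    .checkAlphabet(seqs, allowN = TRUE, what = "read")

    total_raw <- nrow(reads)
    if (total_raw > 0) {
        qmean <- vapply(reads$qual, function(q)
            mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
        nfrac <- vapply(strsplit(seqs, ""), function(b) mean(b == "N"),
                        numeric(1))
        hq <- qmean >= min_mean_q & nfrac <= max_n_frac
    } else hq <- logical(0)
    seqs <- seqs[hq]
    ids <- reads$id[hq]
    nhq <- length(seqs)

    category <- rep(NA_character_, nhq)
    inserts <- rep(NA_character_, nhq)
    if (nhq > 0) {
        pos <- .findAdapter3(seqs, adapter3, max_start = max_len + 1L)
        category[is.na(pos)] <- "adapter3_null"
        ins_len <- pos - 1L
        inserts <- substr(seqs, 1L, ifelse(is.na(ins_len), 0L, ins_len))
        todo <- is.na(category)
        category[todo & ins_len == 0L] <- "insert_null"
        todo <- is.na(category)
        if (any(todo)) {
            mm5 <- .prefixMismatches(inserts[todo], substr(adapter5, 1, 8))
            contam <- !is.na(mm5) & mm5 <= 1L
            category[todo][contam] <- "adapter5_contam"
        }
        todo <- is.na(category)
        if (any(todo)) {
            fracA <- vapply(strsplit(inserts[todo], ""),
                            function(b) mean(b == "A"), numeric(1))
            category[todo][fracA >= polyA_threshold] <- "polyA"
        }
        todo <- is.na(category)
        category[todo & ins_len < min_len] <- "short_lt18"
        category[is.na(category)] <- "clean"
    }

    counts <- vapply(.CLEAN_CATEGORIES, function(k) sum(category == k),
                     numeric(1))
    report <- new("CleaningReport",
                  counts = c(total_raw = total_raw, high_quality = nhq,
                             counts))
    keep <- category == "clean"
    clean <- DNAStringSet(setNames(inserts[keep], ids[keep]))
    list(clean = clean, report = report,
         assignments = data.frame(id = ids, category = category,
                                  stringsAsFactors = FALSE))
}

#' Build a cleaning report from category counts
#'
#' Derives the clean-read count as the high-quality count minus the five
#' removal categories and attaches half-up-rounded percentages, so a
#' published accounting table can be reproduced from its removal counts
#' alone.
#'
#' @param category_counts named numeric vector with \code{high_quality},
#'   the removal categories (\code{adapter3_null}, \code{insert_null},
#'   \code{adapter5_contam}, \code{short_lt18}, \code{polyA}) and
#'   optionally \code{total_raw} (defaults to \code{high_quality}) and
#'   \code{clean} (checked for consistency when supplied)
#' @return a \linkS4class{CleaningReport}
#' @examples
#' r <- summarizeCleaning(c(high_quality = 1000, adapter3_null = 10,
#'                          insert_null = 0, adapter5_contam = 5,
#'                          short_lt18 = 5, polyA = 0))
#' cleaningCounts(r)[["clean"]]   # 980
#' @export
summarizeCleaning <- function(category_counts) {
    cc <- category_counts
    removed <- c("adapter3_null", "insert_null", "adapter5_contam",
                 "short_lt18", "polyA")
    need <- c("high_quality", removed)
    if (!all(need %in% names(cc)))
        stop("missing counts: ",
             paste(setdiff(need, names(cc)), collapse = ", "))
    if (any(cc < 0)) stop("counts must be >= 0")
    hq <- cc[["high_quality"]]
    clean <- hq - sum(cc[removed])
    if (clean < 0)
        stop("removed categories exceed the high-quality count")
    if ("clean" %in% names(cc) && abs(cc[["clean"]] - clean) > 0.5)
        stop("supplied clean count (", cc[["clean"]],
             ") inconsistent with derived value (", clean, ")")
    total <- if ("total_raw" %in% names(cc)) cc[["total_raw"]] else hq
    new("CleaningReport",
        counts = c(total_raw = unname(total), high_quality = unname(hq),
                   cc[removed], clean = unname(clean)))
}

#' Collapse clean reads into unique tags with counts
#'
#' @param reads DNAStringSet or character vector of clean inserts
#' @return a \linkS4class{TagSet} ordered by (count desc, sequence asc);
#'   the counts sum to the number of input reads
#' @export
collapseUnique <- function(reads) {
    reads <- as.character(reads)
    if (length(reads) == 0) return(tagSet(character(0), integer(0)))
    tab <- table(reads)
    tagSet(names(tab), as.integer(tab))
}

#' Write unique tags as FASTA with counts in the headers
#'
#' Headers follow the collapsed-read convention \code{tag<i>_x<count>}.
#'
#' @param tags a \linkS4class{TagSet}
#' @param path output FASTA path
#' @return invisibly, the path
#' @export
writeTagFasta <- function(tags, path) {
    s <- tagSequences(tags)
    names(s) <- sprintf("tag%d_x%d", seq_along(s), tagCounts(tags))
    writeXStringSet(s, path)
    invisible(path)
}

#' Read a tag FASTA written by \code{writeTagFasta}
#'
#' @param path FASTA path with \code{tag<i>_x<count>} headers
#' @return a \linkS4class{TagSet}
#' @export
readTagFasta <- function(path) {
    s <- readDNAStringSet(path)
    counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(s)))
    if (anyNA(counts))
        stop("headers do not follow the tag<i>_x<count> convention")
    tagSet(as.character(s), counts)
}
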