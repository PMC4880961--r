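#' @include read-processing.R annotation.R novel-mirna.R qpcr.R
NULL

.readFixture <- function(path, intCols, seqCols = character(0),
                         dashOk = character(0)) {
    if (!file.exists(path)) stop("fixture not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    for (cn in intCols) {
        raw <- df[[cn]]
        ok <- grepl("^(NA|-|[0-9]+)$", raw)
        if (any(!ok))
            stop("malformed count in '", basename(path), "' line ",
                 which(!ok)[1] + 1L, " (", raw[which(!ok)[1]], ")")
        df[[cn]] <- suppressWarnings(as.numeric(raw))
    }
    for (cn in seqCols) {
        v <- df[[cn]]
        idx <- which(!(cn %in% dashOk & v == "-"))
        bad <- idx[!grepl("^[ACGTU]+$", v[idx])]
        if (length(bad))
            stop("invalid sequence in '", basename(path), "' line ",
                 bad[1] + 1L)
    }
    df
}

#' Parse the bundled summary-table fixtures
#'
#' Reads the three tab-separated fixture tables shipped with the package
#' (read-cleaning accounting, conserved miRNA families, and novel miRNAs
#' with arm-specific sequences), validates counts and sequence alphabets,
#' and returns typed data.frames.
#'
#' @param dir directory holding the fixtures (default: the package's
#'   extdata)
#' @return list with \code{cleaning} (read_type, count, percent),
#'   \code{families} (family, count, sequence, mirbase_ref) and
#'   \code{novel} (mirna_id, count, seq_5p, seq_3p; exactly one arm
#'   populated per row)
#' @export
parsePaperFixtures <- function(dir = system.file("extdata",
                                                 package = "sRNAkit")) {
    cleaning <- .readFixture(file.path(dir, "table1_cleaning.tsv"),
                             intCols = "count")
    cleaning$percent <- suppressWarnings(as.numeric(cleaning$percent))
    families <- .readFixture(file.path(dir, "table2_families.tsv"),
                             intCols = "count", seqCols = "sequence")
    novel <- .readFixture(file.path(dir, "table3_novel.tsv"),
                          intCols = "count",
                          seqCols = c("seq_5p", "seq_3p"),
                          dashOk = c("seq_5p", "seq_3p"))
    both <- (novel$seq_5p != "-") + (novel$seq_3p != "-")
    if (any(both != 1L))
        stop("novel-miRNA fixture rows must populate exactly one arm")
    list(cleaning = cleaning, families = families, novel = novel)
}

#' CleaningReport reconstructed from the bundled accounting fixture
#'
#' Feeds the fixture's removal counts through
#' \code{\link{summarizeCleaning}}, re-deriving the clean-read count and
#' all percentages rather than copying them.
#'
#' @param dir fixture directory (default: the package's extdata)
#' @return a \linkS4class{CleaningReport}
#' @export
fixtureCleaningReport <- function(dir = system.file("extdata",
                                                    package = "sRNAkit")) {
    cl <- parsePaperFixtures(dir)$cleaning
    cts <- setNames(cl$count, cl$read_type)
    summarizeCleaning(cts[c("total_raw", "high_quality", "adapter3_null",
                            "insert_null", "adapter5_contam",
                            "short_lt18", "polyA")])
}

#' The bundled conserved mature miRNA catalogue as a reference set
#'
#' @param dir fixture directory (default: the package's extdata)
#' @return named \link[Biostrings]{DNAStringSet} (names are the source
#'   catalogue entries, e.g. "ath-miR157a")
#' @export
conservedMatureCatalogue <- function(dir = system.file("extdata",
                                                       package = "sRNAkit")) {
    fam <- parsePaperFixtures(dir)$families
    DNAStringSet(setNames(.toDna(fam$sequence), fam$mirbase_ref))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
    path
}

#' Run the full small RNA analysis pipeline
#'
#' Orchestrates cleaning, tag collapsing, composition statistics,
#' annotation, conserved-family aggregation, novel precursor calling and
#' qPCR quantification, writing one tab-separated table per stage plus a
#' JSON run manifest.  Stages whose inputs are absent are skipped.
#' Re-running with the same inputs and seed reproduces byte-identical
#' outputs.
#'
#' @param reads FASTQ path or a reads data.frame (id, seq, qual); NULL
#'   skips the read stages
#' @param genome FASTA path or DNAStringSet; NULL skips novel calling
#' @param mature_refs named DNAStringSet of known mature miRNAs (default:
#'   the bundled conserved catalogue)
#' @param ncrna_refs optional named list of structural RNA reference sets
#'   (priority-ordered), prepended to the mature catalogue for
#'   classification
#' @param ct_table data.frame (gene, tissue, replicate, ct) or TSV path;
#'   NULL skips qPCR
#' @param reference_gene,calibrator_tissue qPCR normalisation settings
#' @param adapter3,adapter5 adapters for cleaning
#' @param out_dir output directory (created if needed)
#' @param seed integer seed recorded in the manifest
#' @param family_floor minimum family count retained (default 500)
#' @param thresholds precursor thresholds, see
#'   \code{\link{precursorThresholds}}
#' @return invisibly, a list with every stage result and the manifest
#' @export
runPipeline <- function(reads = NULL, genome = NULL,
                        mature_refs = conservedMatureCatalogue(),
                        ncrna_refs = NULL, ct_table = NULL,
                        reference_gene = "rRNA5.8S",
                        calibrator_tissue = "leaf",
                        adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                        out_dir = tempfile("srnakit_run_"), seed = 1L,
                        family_floor = 500,
                        thresholds = precursorThresholds()) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "sRNAkit",
                     version = as.character(
                         utils::packageVersion("sRNAkit")),
                     seed = as.integer(seed), stages = list())
    res <- list(out_dir = out_dir)
    stage <- function(name, ...) {
        manifest$stages[[name]] <<- list(...)
    }

    tags <- NULL
    if (!is.null(reads)) {
        cl <- tryCatch(cleanReads(reads, adapter3 = adapter3,
                                  adapter5 = adapter5),
                       error = function(e)
                           stop("stage 'clean' failed: ",
                                conditionMessage(e), call. = FALSE))
        res$cleaning <- cl$report
        .writeTsv(as.data.frame(cl$report),
                  file.path(out_dir, "cleaning_report.tsv"))
        cts <- cleaningCounts(cl$report)
        stage("clean", reads_in = unname(cts[["total_raw"]]),
              high_quality = unname(cts[["high_quality"]]),
              clean = unname(cts[["clean"]]))
        tags <- collapseUnique(cl$clean)
        res$tags <- tags
        if (length(tags) > 0) {
            writeTagFasta(tags, file.path(out_dir, "unique_tags.fa"))
            ld <- lengthDistribution(tags)
            .writeTsv(ld, file.path(out_dir, "length_distribution.tsv"))
            res$length_distribution <- ld
            fb <- firstBaseBias(tags)
            .writeTsv(data.frame(length = rownames(fb), fb,
                                 check.names = FALSE),
                      file.path(out_dir, "first_base_bias.tsv"))
            res$first_base_bias <- fb
        }
        stage("collapse", unique_tags = length(tags),
              reads_collapsed = sum(tagCounts(tags)))
    }

    ann <- NULL
    if (!is.null(tags) && length(tags) > 0) {
        refs <- c(if (!is.null(ncrna_refs)) ncrna_refs,
                  list(mature_miRNA = mature_refs))
        ann <- tryCatch(classifyTags(tags, refs),
                        error = function(e)
                            stop("stage 'annotate' failed: ",
                                 conditionMessage(e), call. = FALSE))
        res$annotations <- ann
        .writeTsv(ann, file.path(out_dir, "annotations.tsv"))
        mir <- ann[ann$class == "mature_miRNA", , drop = FALSE]
        if (nrow(mir) > 0) {
            mb <- do.call(rbind, lapply(mir$tag, matchMirbase,
                                        mature_refs = mature_refs))
            mb$count <- mir$count
            fam <- aggregateFamilies(mb, floor = family_floor)
            res$families <- fam
            .writeTsv(fam, file.path(out_dir, "family_table.tsv"))
        }
        stage("annotate",
              classes = as.list(table(ann$class)),
              families = if (!is.null(res$families))
                  nrow(res$families) else 0L)
    }

    if (!is.null(tags) && length(tags) > 0 && !is.null(genome)) {
        nov <- tryCatch(
            callNovelMirnas(tags, genome, annotations = ann,
                            thresholds = thresholds),
            error = function(e) stop("stage 'novel' failed: ",
                                     conditionMessage(e), call. = FALSE))
        res$novel <- nov$calls
        .writeTsv(nov$calls, file.path(out_dir, "novel_mirnas.tsv"))
        stage("novel", candidates = length(nov$candidates),
              accepted = nrow(nov$calls))
    }

    if (!is.null(ct_table)) {
        if (is.character(ct_table))
            ct_table <- read.delim(ct_table, stringsAsFactors = FALSE)
        expr <- tryCatch(
            quantifyExpression(ct_table, reference_gene,
                               calibrator_tissue),
            error = function(e) stop("stage 'qpcr' failed: ",
                                     conditionMessage(e), call. = FALSE))
        res$expression <- expr
        .writeTsv(expr, file.path(out_dir, "expression.tsv"))
        stage("qpcr", conditions = nrow(expr))
    }

    res$manifest <- manifest
    write_json(manifest, file.path(out_dir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(res)
}
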