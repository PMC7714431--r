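## End-to-end "replay" of the analysis: simulate -> enrich -> ctd-align ->
## codon-bias, each stage reading the previous stage's declared files, with
## a run manifest for reproducibility.

.stageFiles <- list(
    simulate     = c("genome.fasta", "repeats.bed", "reads.fasta",
                     "placements.tsv"),
    enrich       = c("enrichment.tsv", "contigs.tsv"),
    `ctd-align`  = c("alignment.txt", "alignment.tsv"),
    `codon-bias` = c("bias.tsv", "codon_usage.tsv"))

.needUpstream <- function(stage, outDir, files) {
    for (f in files) {
        p <- file.path(outDir, f)
        if (!file.exists(p))
            stop("stage '", stage, "': missing upstream file ", p)
    }
    invisible(TRUE)
}

#' Default demonstration pipeline configuration
#'
#' A small two-family experiment: a CTD-codon-like satellite (147-bp units,
#' seven reverse-translated heptads each) and a CA simple repeat, both
#' selection-weighted above background.
#'
#' @param seed integer seed.
#' @return A [SimConfig-class].
#' @export
defaultPipelineConfig <- function(seed = 101L) {
    simConfig(genomeLength = 20000L,
              families = list(
                  repeatFamily("ACRO1like", unitLength = 147L, copies = 4L,
                               strand = "both", weight = 30,
                               builder = "ctd"),
                  repeatFamily("CAsimple", unitLength = 60L, copies = 5L,
                               strand = "sense", weight = 10,
                               builder = "simple", motif = "CA")),
              readCount = 2000L, readLengthRange = c(30L, 200L),
              noise = 0.005, seed = as.integer(seed))
}

#' Run the full analysis pipeline
#'
#' Chains the stages \code{simulate} (synthetic genome + affinity-weighted
#' read pool), \code{enrich} (family counts, fold enrichment, contig
#' stacks), \code{ctd-align} (translate the CTD-like family's first
#' annotated unit in three frames and align the best frame against the CTD)
#' and \code{codon-bias} (composition bias test + codon usage) in order.
#' Each stage reads the previous stage's files from \code{outDir}; a failure
#' in stage k leaves earlier outputs intact. A \code{manifest.json} with
#' config, seeds, package version and file digests is written at the end.
#' Two runs with the same config and seed produce byte-identical tables.
#'
#' @param config a [SimConfig-class] (e.g. [defaultPipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @param nSets Monte-Carlo replicates for the bias test.
#' @param ctdHeptads number of CTD heptads in the alignment reference.
#' @param quiet suppress progress messages.
#' @return Invisibly, \code{outDir}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        stages = c("simulate", "enrich", "ctd-align",
                                   "codon-bias"),
                        nSets = 1000L, ctdHeptads = 26L, quiet = FALSE) {
    stopifnot(is(config, "SimConfig"), length(stages) >= 1L)
    stages <- match.arg(stages, names(.stageFiles), several.ok = TRUE)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    say <- function(...) if (!quiet) message("[rapscan] ", ...)

    if ("simulate" %in% stages) {
        say("stage simulate: genome ", config@genomeLength, " bp, ",
            config@readCount, " reads")
        gen <- buildGenome(config)
        pool <- sampleReads(gen$genome, gen$truth, config)
        writeFasta(gen$genome, file.path(outDir, "genome.fasta"))
        writeRepeatBed(gen$annotation, file.path(outDir, "repeats.bed"))
        writeFasta(pool$reads, file.path(outDir, "reads.fasta"))
        writePlacements(pool$placements,
                        file.path(outDir, "placements.tsv"))
    }

    if ("enrich" %in% stages) {
        .needUpstream("enrich", outDir,
                      c("placements.tsv", "repeats.bed", "genome.fasta"))
        say("stage enrich")
        placements <- readPlacements(file.path(outDir, "placements.tsv"))
        annot <- readRepeatBed(file.path(outDir, "repeats.bed"))
        genome <- readDnaFasta(file.path(outDir, "genome.fasta"))
        counts <- assignReads(placements, annot)
        enr <- foldEnrichment(counts, totalReads = length(placements),
                              genomeBp = sum(Biostrings::width(genome)))
        writeTsv(enr, file.path(outDir, "enrichment.tsv"))
        stacks <- contigStacks(placements,
                               chromLengths = setNames(
                                   Biostrings::width(genome),
                                   names(genome)))
        writeTsv(stacks, file.path(outDir, "contigs.tsv"))
    }

    if ("ctd-align" %in% stages) {
        .needUpstream("ctd-align", outDir, c("genome.fasta", "repeats.bed"))
        say("stage ctd-align")
        genome <- readDnaFasta(file.path(outDir, "genome.fasta"))
        annot <- readRepeatBed(file.path(outDir, "repeats.bed"))
        ctdFam <- vapply(config@families, function(f)
            f$builder == "ctd", logical(1))
        if (!any(ctdFam))
            stop("stage 'ctd-align': no family with the 'ctd' builder")
        famName <- config@families[[which(ctdFam)[1L]]]$name
        unitGr <- annot[mcols(annot)$family == famName][1L]
        unit <- subseq(genome[[as.character(seqnames(unitGr))]],
                       start(unitGr), end(unitGr))
        if (as.character(strand(unitGr)) == "-")
            unit <- reverseComplement(unit)
        frames <- translateThreeFrames(DNAStringSet(setNames(
            as.character(unit), famName)))
        ctd <- as.character(ctdRepeat(ctdHeptads))
        best <- NULL; bestFrame <- NA_integer_
        for (f in 0:2) {
            pep <- gsub("[*X]", "", as.character(frames[[f + 1L]][[1L]]))
            if (nchar(pep) < 3L) next
            cand <- bestCtdFragment(pep, ctd)
            if (is.null(best) ||
                cand$alignment@score > best$alignment@score) {
                best <- cand; bestFrame <- f
            }
        }
        if (is.null(best)) stop("stage 'ctd-align': unit untranslatable")
        al <- best$alignment
        txt <- c(paste0("# query=", famName, " frame=", bestFrame,
                        " fragment_start=", best$fragmentStart,
                        " score=", al@score,
                        " identities=", al@identities, "/",
                        al@alignedLength),
                 al@alignedA,
                 paste(ifelse(strsplit(al@alignedA, "")[[1L]] ==
                              strsplit(al@alignedB, "")[[1L]] &
                              strsplit(al@alignedA, "")[[1L]] != "-",
                              "|", " "), collapse = ""),
                 al@alignedB)
        writeLines(txt, file.path(outDir, "alignment.txt"))
        writeTsv(data.frame(query_id = famName, frame = bestFrame,
                            fragment_start = best$fragmentStart,
                            score = al@score, identities = al@identities,
                            aligned_length = al@alignedLength),
                 file.path(outDir, "alignment.tsv"))
    }

    if ("codon-bias" %in% stages) {
        .needUpstream("codon-bias", outDir, "reads.fasta")
        say("stage codon-bias: nSets=", nSets)
        reads <- readDnaFasta(file.path(outDir, "reads.fasta"))
        reads <- reads[Biostrings::width(reads) >= 5L]
        bt <- biasTest(reads, bg = backgroundModel(config@bg),
                       nSets = nSets, seed = config@seed + 2L)
        writeTsv(data.frame(observed_jsd = bt@observedJSD,
                            null_mean = bt@null@mean,
                            null_sd = bt@null@sd, z = bt@z,
                            p_empirical = bt@pEmpirical,
                            p_gaussian = bt@pGaussian),
                 file.path(outDir, "bias.tsv"))
        writeTsv(codonUsage(reads), file.path(outDir, "codon_usage.tsv"))
    }

    manifest <- list(
        command = "runPipeline",
        stages = stages,
        seed = config@seed,
        package_version = as.character(packageVersion("rapscan")),
        config = list(genomeLength = config@genomeLength,
                      bg = as.numeric(config@bg),
                      families = config@families,
                      readCount = config@readCount,
                      readLengthRange = config@readLengthRange,
                      noise = config@noise, seed = config@seed,
                      nSets = nSets, ctdHeptads = ctdHeptads),
        timestamp = format(Sys.time(), tz = "UTC"),
        digests = as.list(md5sum(list.files(outDir, full.names = TRUE,
                                            pattern = "\\.(tsv|bed|fasta|txt)$"))))
    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
    say("done: ", outDir)
    invisible(outDir)
}
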