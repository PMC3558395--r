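## End-to-end study pipelines and report serialization.
##
## The two pipelines tie the modules into the two experiments: the
## second-block study (stereoisomer enumeration -> truncated hashes ->
## subsampling collision counts vs. theory) and the first-block study
## (skeleton population -> forged keys -> positional letter frequencies
## and sequence-occurrence scan vs. the layout calculus).  The reporting
## layer only formats numbers produced by the module functions; every
## report embeds its full configuration and seed, so two runs with the
## same config are byte-identical.

.DEFAULT_SEQUENCES <- c("ABCD", "FMGL", "LGRC", "RBCQ",
                        "EDNA", "EGPS", "EKPH", "EJDO",
                        "TBAC", "TKIL", "TRPC", "TSBF",
                        "ZAMR", "ZDKL", "ZSBC", "ZIII")

.fmt4 <- function(x) sprintf("%.4f", x)          # means/expectations
.fmtSci <- function(x) sprintf("%.4e", x)        # probabilities

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the second-block collision study
#'
#' Emulates the exhaustive second-block protocol at configurable scale:
#' enumerate the stereoisomers of a skeleton with `nStereo` binary
#' stereogenic elements, hash every isomer layer to a 37-bit value, then
#' for each subset size in `kValues` draw `m` random subsets, count
#' same-hash pairs, and compare the averages to \eqn{k(k-1)/2p}.
#'
#' The defaults are a reduced-scale rendition of the flagship experiment
#' (2^26 isomers, subset sizes up to the full set): `nStereo = 22` with a
#' 1/16-scaled k-grid keeps the default run on a laptop-minutes budget
#' while preserving the statistics under test, which depend only on
#' \eqn{k(k-1)/2p}.  Pass `nStereo = 26` and the full-size grid for the
#' full-scale campaign.
#'
#' @param nStereo stereogenic element count (population size `2^nStereo`).
#' @param kValues subset sizes; default scales the classic grid by 1/16.
#' @param m repetitions per subset size.
#' @param seed root seed recorded in all outputs.
#' @param outDir directory for report files (created if needed); `NULL`
#'   skips writing.
#' @param skeletonId,formulaTag labels for the synthetic skeleton.
#' @return invisibly, a list with the comparison `table` (data.frame),
#'   the per-k [ExperimentResult-class] list `experiments`, and the
#'   written file paths.
#' @examples
#' st <- runSecondBlockStudy(nStereo = 14, kValues = c(500, 2000),
#'                           m = 50, outDir = NULL)
#' st$table
#' @export
runSecondBlockStudy <- function(nStereo = 22L,
                                kValues = c(625, 3125, 6250, 15625,
                                            23125, 31250, 62500, 125000),
                                m = 1000L, seed = 42L, outDir = NULL,
                                skeletonId = "spongistatin-like",
                                formulaTag = "C49H74O17") {
  spec <- skeletonSpec(skeletonId, nStereo, formulaTag)
  model <- birthdayModel(bits = 37)
  pop <- hashStereoPopulation(spec, bits = 37L)
  tab <- theoryComparisonTable(pop, kValues, m = m, seed = seed,
                               model = model)
  exps <- attr(tab, "experiments")

  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    out <- data.frame(k = tab$k, expected = .fmt4(tab$expected),
                      observed_mean = .fmt4(tab$observed_mean),
                      m = tab$m)
    files <- c(files, .writeTSV(out, file.path(outDir,
                                               "second_block_table.tsv")))
    report <- list(
      config = list(study = "second_block", nStereo = nStereo,
                    kValues = kValues, m = m, seed = seed,
                    populationSize = length(pop),
                    skeletonId = skeletonId, formulaTag = formulaTag),
      results = lapply(exps, function(e) list(
        k = e@k, m = e@m, theory = e@theory,
        mean_collisions = e@meanCollisions,
        mean_duplicates = e@meanDuplicates,
        histogram = as.list(e@histogram),
        running_means = e@runningMeans)))
    jpath <- file.path(outDir, "second_block_histograms.json")
    write_json(report, jpath, auto_unbox = TRUE, digits = NA)
    files <- c(files, jpath)
  }
  invisible(list(table = tab, experiments = exps, files = files,
                 population = pop))
}

#' Run the first-block statistics study
#'
#' Emulates the first-block protocol: generate `nKeys` distinct skeleton
#' identifier strings, forge their keys (65-bit truncated SHA-256 into
#' the first-block layout), measure positional letter frequencies, and
#' count occurrences of the predefined 4-letter `sequences`, comparing
#' each with the layout-derived expectation.  Processing is chunked so
#' the key list is never held in memory at once.
#'
#' @param nKeys number of keys to forge.
#' @param sequences letter sequences to scan for (default: the classic
#'   sixteen 4-letter probes).
#' @param seed population seed.
#' @param outDir directory for report files; `NULL` skips writing.
#' @param chunkSize keys per streaming chunk.
#' @param formulaTag free-text molecular-formula stand-in.
#' @param measureFrequencies also accumulate the positional
#'   letter-frequency matrix and infer unit boundaries (adds roughly half
#'   the runtime; the sequence scan does not need it).
#' @return invisibly, a list with the occurrence `table`
#'   (sequence, experiment, theory, ratio), the [FrequencyMatrix-class]
#'   `frequencies`, the inferred unit boundaries, and written file paths.
#' @examples
#' st <- runFirstBlockStudy(nKeys = 2e4, outDir = NULL)
#' head(st$table)
#' @export
runFirstBlockStudy <- function(nKeys = 1e6,
                               sequences = .DEFAULT_SEQUENCES,
                               seed = 42L, outDir = NULL,
                               chunkSize = 2^20,
                               formulaTag = "C8H8Cl3F5",
                               measureFrequencies = TRUE) {
  layout <- block1Layout()
  ab <- layout@alphabet
  counts <- matrix(0, nrow = length(ab), ncol = blockLength(layout),
                   dimnames = list(ab, seq_len(blockLength(layout))))
  occ <- setNames(numeric(length(sequences)), sequences)
  tables <- lapply(layout@units, validStrings)
  from <- 0
  while (from < nKeys) {
    take <- min(chunkSize, nKeys - from)
    skel <- generateSkeletonPopulation(take, seed = seed,
                                       formulaTag = formulaTag,
                                       from = from)
    idx <- .hashBlock1Indices(skel)
    # per-start-position overlapping counts, same convention as
    # observedOccurrences() (equivalence is property-tested)
    occ <- occ + .Call(C_scan_indices, idx, tables, sequences)
    if (measureFrequencies) {
      fm <- letterPositionFrequencies(.indicesToBlocks(idx, layout),
                                      layout)
      counts <- counts + fm@counts
    }
    from <- from + take
  }
  freq <- if (measureFrequencies)
    new("FrequencyMatrix", counts = counts, nKeys = nKeys,
        nMalformed = 0, referenceLetter = "A") else NULL
  theo <- vapply(sequences, expectedOccurrences, numeric(1),
                 nKeys = nKeys, layout = layout)
  tab <- data.frame(sequence = sequences,
                    experiment = as.numeric(occ),
                    theory = theo,
                    ratio = as.numeric(occ) / theo,
                    probability = theo / nKeys,
                    row.names = NULL)
  bounds <- if (measureFrequencies) inferUnitBoundaries(freq) else NULL

  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    out <- data.frame(sequence = tab$sequence,
                      experiment = tab$experiment,
                      theory = round(tab$theory),
                      ratio = sprintf("%.3f", tab$ratio),
                      probability = .fmtSci(tab$probability))
    files <- c(files,
               .writeTSV(out, file.path(outDir,
                                        "first_block_sequences.tsv")))
    if (measureFrequencies) {
      nf <- normalizedFrequencies(freq)
      nfd <- data.frame(letter = rownames(nf),
                        apply(nf, 2, .fmt4), check.names = FALSE)
      names(nfd) <- c("letter", paste0("pos", seq_len(ncol(nf))))
      files <- c(files,
                 .writeTSV(nfd, file.path(outDir,
                                          "first_block_frequencies.tsv")))
    }
    report <- list(config = list(study = "first_block", nKeys = nKeys,
                                 sequences = sequences, seed = seed,
                                 formulaTag = formulaTag),
                   unit_boundaries = if (measureFrequencies)
                     as.integer(bounds) else NULL,
                   occurrences = as.list(occ))
    jpath <- file.path(outDir, "first_block_report.json")
    write_json(report, jpath, auto_unbox = TRUE, digits = NA)
    files <- c(files, jpath)
  }
  invisible(list(table = tab, frequencies = freq, boundaries = bounds,
                 files = files))
}
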