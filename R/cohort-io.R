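#' @importFrom utils read.delim write.table
NULL

# Variant_Classification values counted as "mutant": the conventional
# non-silent set. Silent/UTR/Intron/IGR/Flank variants never flip a gene to 1.
#' Non-silent MAF variant classes retained by \code{loadMafMutations}
#' @export
nonSilentClasses <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Translation_Start_Site", "Nonstop_Mutation")

.gisticLabels <- c(`-2` = "deep loss", `-1` = "shallow loss",
                   `0` = "no change", `1` = "gain", `2` = "amplification")

.readMatrixTsv <- function(path, what) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop(sprintf("empty or sample-less %s file: %s", what, path))
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene row(s) in %s: %s", path,
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- genes
  m
}

.part <- function(values, info, event = NULL, fillZero = FALSE) {
  if (nrow(info) == 1L && nrow(values) > 1L)
    info <- info[rep(1L, nrow(values)), , drop = FALSE]
  stopifnot(nrow(info) == nrow(values))
  structure(list(values = values, info = info, event = event,
                 fillZero = fillZero), class = "CohortPart")
}

#' Load a gene x sample expression matrix
#'
#' Reads a tab-delimited matrix (gene identifiers in the first column,
#' sample IDs in the header; gzip transparent) into continuous variables
#' named \code{"<GENE>.<sourceTag>"}. Non-numeric cells become missing.
#'
#' @param path TSV (optionally .gz) file
#' @param sourceTag suffix and source label, e.g. "RNA" or "RPPA"
#' @param source cohort source category; defaults to "mRNA" for tag "RNA",
#'   "RPPA" for tag "RPPA", otherwise the tag itself.
#' @return a cohort part for \code{\link{assembleCohort}}
#' @export
loadExpressionMatrix <- function(path, sourceTag = "RNA", source = NULL) {
  m <- .readMatrixTsv(path, "expression")
  rownames(m) <- paste0(rownames(m), ".", sourceTag)
  if (is.null(source))
    source <- switch(sourceTag, RNA = "mRNA", RPPA = "RPPA", miRNA = "miRNA",
                     sourceTag)
  .part(m, data.frame(source = source, dtype = "continuous"))
}

#' Load somatic mutations from a MAF file
#'
#' Collapses a Mutation Annotation Format table to per-gene binary
#' indicators: a sample is 1 for a gene if it carries at least one variant
#' whose \code{Variant_Classification} is in \code{\link{nonSilentClasses}}.
#' MAF files list only variant-bearing samples, so cohort samples absent
#' from the file are wild-type (0), not missing; at assembly time the
#' indicators are expanded with zeros over the cohort's sample set.
#'
#' @param path MAF file (tab-delimited, gzip transparent)
#' @param genes optional gene filter (Hugo symbols)
#' @param retainClasses variant classes that count as mutant
#' @return a cohort part with variables \code{"<GENE>.Mut"}
#' @export
loadMafMutations <- function(path, genes = NULL,
                             retainClasses = nonSilentClasses) {
  maf <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(maf))
  if (length(miss))
    stop(sprintf("MAF is missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")))
  samples <- sort(unique(as.character(maf$Tumor_Sample_Barcode)))
  maf <- maf[maf$Variant_Classification %in% retainClasses, , drop = FALSE]
  if (!is.null(genes)) maf <- maf[maf$Hugo_Symbol %in% genes, , drop = FALSE]
  gset <- if (is.null(genes)) sort(unique(as.character(maf$Hugo_Symbol))) else
    sort(unique(genes))
  m <- matrix(0, length(gset), length(samples),
              dimnames = list(paste0(gset, ".Mut"), samples))
  if (nrow(maf)) {
    # >=1 retained variant => 1, idempotent over repeated hits
    idx <- cbind(match(paste0(maf$Hugo_Symbol, ".Mut"), rownames(m)),
                 match(as.character(maf$Tumor_Sample_Barcode), samples))
    m[idx] <- 1
  }
  .part(m, data.frame(source = rep("Mutation", nrow(m)),
                      dtype = rep("binary", nrow(m))), fillZero = TRUE)
}

#' Load thresholded copy-number calls (GISTIC by-gene format)
#'
#' Integer codes -2 (deep loss), -1 (shallow loss), 0 (no change),
#' 1 (gain), 2 (amplification); any other code is an error reporting its
#' coordinates.
#'
#' @param path gene x sample TSV of integer codes
#' @return a cohort part with ordinal variables \code{"<GENE>.GISTIC"}
#' @export
loadGisticCnv <- function(path) {
  m <- .readMatrixTsv(path, "CNV")
  bad <- which(!is.na(m) & !(m %in% (-2:2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("CNV code outside {-2..2} at gene '%s', sample '%s' (value %s)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]))
  rownames(m) <- paste0(rownames(m), ".GISTIC")
  info <- data.frame(source = rep("CNV", nrow(m)),
                     dtype = rep("ordinal", nrow(m)))
  info$labels <- replicate(nrow(m), unname(.gisticLabels), simplify = FALSE)
  .part(m, info)
}

#' @describeIn loadGisticCnv label of a GISTIC code (-2..2)
#' @param code integer code(s) in -2..2
#' @export
gisticLabel <- function(code) {
  if (any(!code %in% (-2:2))) stop("GISTIC codes lie in {-2..2}")
  unname(.gisticLabels[as.character(code)])
}

.EVENT_SYNONYMS <- c("dead" = 1, "deceased" = 1, "1" = 1,
                     "alive" = 0, "living" = 0, "censored" = 0, "0" = 0)

#' Load a clinical table with an overall-survival endpoint
#'
#' Numeric columns become continuous variables \code{"<col>.Clinical"},
#' string columns categorical; \code{timeCol}/\code{eventCol} become one
#' survival variable (default id \code{"OS.Survival"}). Events accept 0/1 or
#' dead/alive-style synonyms (case-insensitive).
#'
#' @param path TSV keyed by sample ID in the first column (gzip transparent)
#' @param timeCol,eventCol column names of follow-up time (days, >= 0) and
#'   event status
#' @param survivalId id of the resulting survival variable
#' @return a cohort part
#' @export
loadClinical <- function(path, timeCol = "OS_time", eventCol = "OS_event",
                         survivalId = "OS.Survival") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty clinical file: ", path)
  samples <- as.character(df[[1]])
  if (anyDuplicated(samples)) stop("duplicate sample IDs in clinical file")
  for (cc in c(timeCol, eventCol))
    if (!cc %in% colnames(df))
      stop(sprintf("clinical file lacks column '%s'", cc))
  tt <- suppressWarnings(as.numeric(df[[timeCol]]))
  if (any(tt < 0, na.rm = TRUE)) stop("negative survival time in clinical file")
  evRaw <- tolower(trimws(as.character(df[[eventCol]])))
  ev <- unname(.EVENT_SYNONYMS[evRaw])
  unknown <- !is.na(df[[eventCol]]) & nzchar(evRaw) & is.na(ev)
  if (any(unknown))
    stop(sprintf("unrecognized event value(s): %s",
                 paste(unique(evRaw[unknown]), collapse = ", ")))
  rowsV <- list(); rowsE <- list(); info <- list()
  rowsV[[survivalId]] <- tt
  rowsE[[survivalId]] <- ev
  info[[survivalId]] <- list(source = "Survival", dtype = "survival",
                             labels = NULL)
  other <- setdiff(colnames(df)[-1], c(timeCol, eventCol))
  for (cc in other) {
    col <- df[[cc]]
    id <- paste0(cc, ".Clinical")
    if (is.numeric(col)) {
      rowsV[[id]] <- as.numeric(col)
      info[[id]] <- list(source = "Clinical", dtype = "continuous",
                         labels = NULL)
    } else {
      col <- as.character(col); col[!nzchar(trimws(col))] <- NA
      labs <- sort(unique(col[!is.na(col)]))
      rowsV[[id]] <- as.numeric(match(col, labs))
      info[[id]] <- list(source = "Clinical", dtype = "categorical",
                         labels = labs)
    }
    rowsE[[id]] <- rep(NA_real_, nrow(df))
  }
  v <- do.call(rbind, rowsV); colnames(v) <- samples
  e <- do.call(rbind, rowsE); colnames(e) <- samples
  inf <- data.frame(source = vapply(info, `[[`, "", "source"),
                    dtype = vapply(info, `[[`, "", "dtype"))
  inf$labels <- lapply(info, `[[`, "labels")
  .part(v, inf, event = e)
}

#' Assemble loaded parts into a sample-aligned Cohort
#'
#' Samples are aligned across parts by intersection (default) or union with
#' a missing-value mask, and deterministically sorted. Mutation parts do not
#' restrict the intersection (MAFs list only variant-bearing samples) and
#' are zero-filled over the assembled sample set; if only mutation parts are
#' given their own samples define the cohort.
#'
#' @param ... cohort parts from the load functions
#' @param name cohort name
#' @param samples \code{"intersect"} or \code{"union"}
#' @return a \linkS4class{Cohort}
#' @export
assembleCohort <- function(..., name = "cohort",
                           samples = c("intersect", "union")) {
  parts <- list(...)
  samples <- match.arg(samples)
  if (!length(parts)) stop("at least one loaded part is required")
  stopifnot(all(vapply(parts, inherits, TRUE, "CohortPart")))
  defining <- parts[!vapply(parts, `[[`, TRUE, "fillZero")]
  if (!length(defining)) defining <- parts
  sets <- lapply(defining, function(p) colnames(p$values))
  sampleSet <- if (samples == "intersect") Reduce(intersect, sets) else
    Reduce(union, sets)
  if (!length(sampleSet)) stop("empty sample intersection across parts")
  sampleSet <- sort(sampleSet)
  valRows <- list(); evRows <- list(); infos <- list()
  for (p in parts) {
    v <- matrix(NA_real_, nrow(p$values), length(sampleSet),
                dimnames = list(rownames(p$values), sampleSet))
    hit <- intersect(colnames(p$values), sampleSet)
    v[, hit] <- p$values[, hit, drop = FALSE]
    if (p$fillZero) v[is.na(v)] <- 0
    e <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    if (!is.null(p$event)) e[, hit] <- p$event[, hit, drop = FALSE]
    valRows[[length(valRows) + 1L]] <- v
    evRows[[length(evRows) + 1L]] <- e
    inf <- p$info
    if (is.null(inf$labels)) inf$labels <- replicate(nrow(inf), NULL)
    infos[[length(infos) + 1L]] <- inf
  }
  values <- do.call(rbind, valRows)
  event <- do.call(rbind, evRows)
  if (anyDuplicated(rownames(values)))
    stop(sprintf("duplicate variable id(s) across parts: %s",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", ")))
  info <- data.frame(source = unlist(lapply(infos, `[[`, "source")),
                     dtype = unlist(lapply(infos, `[[`, "dtype")))
  info$labels <- do.call(c, lapply(infos, function(x) as.list(x$labels)))
  cohort(name, values, info, event)
}

.fmt <- function(x) {
  # full-precision decimal text so write -> read round-trips exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a cohort back to its standard file bundle
#'
#' Produces expression TSVs (one per continuous source tag), a MAF, a GISTIC
#' TSV and a clinical TSV that \code{\link{assembleCohort}} re-loads to an
#' identical cohort (values and missing mask preserved exactly).
#'
#' @param x a \linkS4class{Cohort}
#' @param dir output directory (created if needed)
#' @return invisibly, the named list of files written
#' @export
writeCohortFiles <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- rowData(x)
  v <- assay(x, "values")
  files <- list()
  writeMat <- function(ids, stripSuffix, path, fmt = .fmt) {
    genes <- sub(paste0("\\.", stripSuffix, "$"), "", ids)
    df <- data.frame(gene = genes,
                     matrix(vapply(v[ids, , drop = FALSE], fmt, ""),
                            nrow = length(ids)), check.names = FALSE)
    colnames(df) <- c("gene", colnames(x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  for (src in intersect(unique(rd$source), c("mRNA", "miRNA", "RPPA"))) {
    ids <- rownames(x)[rd$source == src & rd$dtype == "continuous"]
    if (!length(ids)) next
    tag <- sub("^.*\\.", "", ids[1])
    f <- file.path(dir, paste0("expression_", tag, ".tsv"))
    files[[src]] <- writeMat(ids, tag, f)
  }
  mutIds <- rownames(x)[rd$source == "Mutation"]
  if (length(mutIds)) {
    mm <- v[mutIds, , drop = FALSE]
    hit <- which(mm == 1, arr.ind = TRUE)
    maf <- data.frame(
      Hugo_Symbol = sub("\\.Mut$", "", mutIds[hit[, 1]]),
      Tumor_Sample_Barcode = colnames(x)[hit[, 2]],
      Variant_Classification = rep("Missense_Mutation", nrow(hit)))
    maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode), , drop = FALSE]
    f <- file.path(dir, "mutations.maf")
    write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files$Mutation <- f
  }
  cnvIds <- rownames(x)[rd$source == "CNV"]
  if (length(cnvIds)) {
    f <- file.path(dir, "cnv_gistic.tsv")
    files$CNV <- writeMat(cnvIds, "GISTIC", f,
                          fmt = function(z) ifelse(is.na(z), "NA",
                                                   sprintf("%d", as.integer(z))))
  }
  clinIds <- rownames(x)[rd$source %in% c("Clinical", "Survival")]
  if (length(clinIds)) {
    df <- data.frame(sample_id = colnames(x))
    for (id in clinIds) {
      k <- match(id, rownames(x))
      if (rd$dtype[k] == "survival") {
        df$OS_time <- .fmt(v[id, ])
        df$OS_event <- ifelse(is.na(assay(x, "event")[id, ]), "NA",
                              sprintf("%d", as.integer(assay(x, "event")[id, ])))
      } else if (rd$dtype[k] == "categorical") {
        labs <- rd$labels[[k]]
        df[[sub("\\.Clinical$", "", id)]] <-
          ifelse(is.na(v[id, ]), "NA", labs[v[id, ]])
      } else {
        df[[sub("\\.Clinical$", "", id)]] <- .fmt(v[id, ])
      }
    }
    f <- file.path(dir, "clinical.tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files$Clinical <- f
  }
  invisible(files)
}

#' Re-load a bundle written by \code{writeCohortFiles}
#'
#' @param dir directory holding the bundle
#' @param name cohort name
#' @return a \linkS4class{Cohort}
#' @export
loadCohortFiles <- function(dir, name = "cohort") {
  parts <- list()
  for (f in list.files(dir, pattern = "^expression_.*\\.tsv$",
                       full.names = TRUE)) {
    tag <- sub("^expression_(.*)\\.tsv$", "\\1", basename(f))
    parts[[length(parts) + 1L]] <- loadExpressionMatrix(f, sourceTag = tag)
  }
  mafF <- file.path(dir, "mutations.maf")
  if (file.exists(mafF))
    parts[[length(parts) + 1L]] <- loadMafMutations(mafF)
  cnvF <- file.path(dir, "cnv_gistic.tsv")
  if (file.exists(cnvF))
    parts[[length(parts) + 1L]] <- loadGisticCnv(cnvF)
  clinF <- file.path(dir, "clinical.tsv")
  if (file.exists(clinF))
    parts[[length(parts) + 1L]] <- loadClinical(clinF)
  if (!length(parts)) stop("no cohort files found in ", dir)
  do.call(assembleCohort, c(parts, list(name = name, samples = "union")))
}
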