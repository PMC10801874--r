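#' Read and validate an sgRNA library table
#'
#' Reads a TSV/CSV guide catalog into a validated `sgrna_library` data frame.
#' Non-targeting control (NTC) guides are identified either by a logical flag
#' column or by a sentinel value in the gene column (empty string, `NA`, or a
#' name listed in `ntc_sentinels`).
#'
#' @param path Path to a delimited file (tab or comma separated, sniffed from
#'   the extension: `.csv` is comma, anything else tab).
#' @param dialect Named list mapping the canonical column names
#'   (`guide_id`, `protospacer`, `gene`, `is_ntc`, `sublibrary`) to the file's
#'   column names. `is_ntc` and `sublibrary` are optional.
#' @param ntc_sentinels Character vector of gene-column values that mark a
#'   guide as non-targeting when no `is_ntc` column is mapped.
#' @return A data frame of class `sgrna_library` with columns `guide_id`,
#'   `protospacer`, `gene` (`NA` for NTCs), `is_ntc`, `sublibrary`.
#' @export
read_library <- function(path,
                         dialect = list(guide_id = "guide_id",
                                        protospacer = "protospacer",
                                        gene = "gene"),
                         ntc_sentinels = c("", "NA", "non-targeting",
                                           "non_targeting", "NTC")) {
  if (!file.exists(path)) stop("library file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- c("guide_id", "protospacer", "gene")
  for (nm in need) {
    col <- dialect[[nm]]
    if (is.null(col) || !col %in% names(tab))
      stop("required column '", nm, "' not resolvable via dialect (looked for '",
           if (is.null(col)) "<unmapped>" else col, "')")
  }
  gene <- tab[[dialect$gene]]
  if (!is.null(dialect$is_ntc) && dialect$is_ntc %in% names(tab)) {
    is_ntc <- tolower(tab[[dialect$is_ntc]]) %in% c("true", "t", "1", "yes")
  } else {
    is_ntc <- is.na(gene) | gene %in% ntc_sentinels
  }
  gene[is_ntc] <- NA_character_
  sublib <- if (!is.null(dialect$sublibrary) && dialect$sublibrary %in% names(tab))
    tab[[dialect$sublibrary]] else NA_character_
  sgrna_library(guide_id = tab[[dialect$guide_id]],
                protospacer = tab[[dialect$protospacer]],
                gene = gene, sublibrary = sublib)
}

#' Construct an sgRNA library from vectors
#'
#' @param guide_id Unique guide identifiers.
#' @param protospacer DNA targeting sequences (A/C/G/T, 18-23 nt typical).
#' @param gene Target gene symbol per guide; `NA` marks a non-targeting
#'   control.
#' @param sublibrary Optional sublibrary label.
#' @return A validated `sgrna_library` data frame.
#' @export
sgrna_library <- function(guide_id, protospacer, gene,
                          sublibrary = NA_character_) {
  if (length(guide_id) == 0L) stop("no guides in library")
  lib <- data.frame(guide_id = as.character(guide_id),
                    protospacer = toupper(as.character(protospacer)),
                    gene = as.character(gene),
                    is_ntc = is.na(gene),
                    sublibrary = as.character(sublibrary),
                    stringsAsFactors = FALSE)
  dup <- unique(lib$guide_id[duplicated(lib$guide_id)])
  if (length(dup))
    stop("duplicate guide_id in library: ", paste(dup, collapse = ", "))
  bad <- grepl("[^ACGT]", lib$protospacer)
  if (any(bad))
    stop("non-DNA protospacer for guide(s): ",
         paste(utils::head(lib$guide_id[bad], 5), collapse = ", "))
  if (!any(lib$is_ntc))
    warning("library contains no non-targeting control guides; ",
            "pseudogene null construction will fail")
  if (!any(!lib$is_ntc))
    warning("library contains no targeting guides")
  class(lib) <- c("sgrna_library", "data.frame")
  lib
}

#' Count guide protospacers in FASTQ reads
#'
#' Assigns each read to at most one guide by exact substring match at a fixed
#' offset: the read substring starting at `offset` (0-based) and as long as a
#' guide's protospacer must equal that protospacer (or its reverse complement
#' when `orientation = "reverse_complement"`). When protospacer lengths vary,
#' the longest matching protospacer wins. No mismatches are tolerated.
#'
#' @param fastq Path(s) to FASTQ files (gzip transparent), concatenated.
#' @param library An `sgrna_library`.
#' @param offset Integer, 0-based position of the protospacer in the read.
#' @param orientation `"forward"` to match protospacers as given,
#'   `"reverse_complement"` to match their reverse complements.
#' @return A list with `counts` (named integer vector over all library
#'   guides, zeros for unseen guides) and `report` (list with `total_reads`,
#'   `matched`, `unmatched`, `match_rate`).
#' @export
count_guides <- function(fastq, library, offset = 0L,
                         orientation = c("forward", "reverse_complement")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(library, "sgrna_library"), offset >= 0L)
  proto <- library$protospacer
  if (anyDuplicated(proto))
    stop("ambiguous library: protospacer shared by guides ",
         paste(library$guide_id[proto %in% proto[duplicated(proto)]],
               collapse = ", "))
  key <- if (orientation == "reverse_complement")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(proto)))
  else proto

  reads <- character(0)
  for (f in fastq) {
    if (!file.exists(f)) stop("FASTQ not found: ", f)
    rs <- tryCatch(
      Biostrings::readDNAStringSet(f, format = "fastq"),
      error = function(e) {
        # an empty FASTQ is a legitimate degenerate input, not a failure
        if (file.size(f) == 0 ||
            grepl("no lines|empty", conditionMessage(e), ignore.case = TRUE))
          Biostrings::DNAStringSet()
        else stop(e)
      })
    reads <- c(reads, as.character(rs))
  }
  n_total <- length(reads)
  counts <- integer(nrow(library))
  names(counts) <- library$guide_id
  matched <- 0L
  if (n_total > 0) {
    assigned <- rep(NA_integer_, n_total)
    # longest protospacer first so nested prefixes resolve deterministically
    for (L in sort(unique(nchar(key)), decreasing = TRUE)) {
      idx <- which(nchar(key) == L)
      sub <- substr(reads, offset + 1L, offset + L)
      hit <- match(sub, key[idx])
      take <- is.na(assigned) & !is.na(hit)
      assigned[take] <- idx[hit[take]]
    }
    tab <- tabulate(assigned, nbins = nrow(library))
    counts[] <- tab
    matched <- sum(!is.na(assigned))
  }
  if (n_total > 0 && matched == 0L)
    warning("zero reads matched the library; check offset/orientation")
  list(counts = counts,
       report = list(total_reads = n_total, matched = matched,
                     unmatched = n_total - matched,
                     match_rate = if (n_total > 0) matched / n_total else NA_real_))
}

#' Merge per-sample count columns into a count matrix
#'
#' @param columns Named list of per-sample count vectors (names are sample
#'   ids; each vector named by guide id). Guides absent from a column are
#'   stored as 0.
#' @param design A `screen_design` data frame; columns are ordered to follow
#'   `design$sample_id`.
#' @param library An `sgrna_library` defining the row universe.
#' @return Integer matrix, guides x samples, rownames = guide ids.
#' @export
merge_counts <- function(columns, design, library) {
  stopifnot(inherits(library, "sgrna_library"))
  miss <- setdiff(design$sample_id, names(columns))
  if (length(miss))
    stop("design sample(s) without a count column: ",
         paste(miss, collapse = ", "))
  guides <- library$guide_id
  m <- matrix(0L, nrow = length(guides), ncol = nrow(design),
              dimnames = list(guides, design$sample_id))
  for (s in design$sample_id) {
    v <- columns[[s]]
    extra <- setdiff(names(v), guides)
    if (length(extra))
      stop("count column '", s, "' has guides not in library: ",
           paste(utils::head(extra, 5), collapse = ", "))
    m[names(v), s] <- as.integer(v)
  }
  if (any(m < 0)) stop("negative counts")
  m
}

#' Construct a screen design table
#'
#' One row per sequenced sample. Every replicate within a
#' (dye, condition, treatment) stratum must contain exactly one `high` and
#' one `low` sorted fraction.
#'
#' @param dye Reporter dye, e.g. `"MitoSOX"`, `"DCFDA"`, `"MitoNeoD"`,
#'   `"ATP-FRET"`.
#' @param condition Metabolic substrate condition: `"respiratory"`,
#'   `"glycolytic"`, or `"basal"`.
#' @param treatment Treatment label (`"none"`, `"Trolox_1mM"`, ...).
#' @param n_replicates Number of replicate sorts.
#' @return A `screen_design` data frame with columns `sample_id`, `fraction`,
#'   `dye`, `condition`, `treatment`, `replicate`.
#' @export
screen_design <- function(dye = "MitoSOX", condition = "respiratory",
                          treatment = "none", n_replicates = 2L) {
  stopifnot(n_replicates >= 1L)
  reps <- rep(seq_len(n_replicates), each = 2L)
  frac <- rep(c("high", "low"), n_replicates)
  d <- data.frame(
    sample_id = sprintf("%s_%s_%s_rep%d_%s", dye, condition, treatment,
                        reps, frac),
    fraction = frac, dye = dye, condition = condition,
    treatment = treatment, replicate = reps, stringsAsFactors = FALSE)
  validate_design(d)
}

#' Validate a screen design
#'
#' @param design Data frame with columns `sample_id`, `fraction`, `dye`,
#'   `condition`, `treatment`, `replicate`.
#' @return The design, with class `screen_design`, invisibly checked.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "fraction", "dye", "condition", "treatment",
            "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!all(design$fraction %in% c("high", "low")))
    stop("fraction must be 'high' or 'low'")
  key <- interaction(design$dye, design$condition, design$treatment,
                     design$replicate, drop = TRUE)
  for (k in levels(key)) {
    fr <- design$fraction[key == k]
    if (sum(fr == "high") != 1L || sum(fr == "low") != 1L)
      stop("stratum/replicate ", k,
           " must have exactly one high and one low sample")
  }
  class(design) <- unique(c("screen_design", class(design)))
  design
}

#' Read a screen design from YAML or CSV
#'
#' @param path A `.yaml`/`.yml` file holding a list of sample records, or a
#'   CSV/TSV with the design columns.
#' @return A validated `screen_design`.
#' @export
read_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    if (!is.null(recs$samples)) recs <- recs$samples
    d <- do.call(rbind, lapply(recs, function(r)
      data.frame(sample_id = r$sample_id, fraction = r$fraction, dye = r$dye,
                 condition = r$condition, treatment = r$treatment,
                 replicate = as.integer(r$replicate),
                 stringsAsFactors = FALSE)))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  }
  validate_design(d)
}

#' Write / read a count matrix as TSV
#'
#' Plain TSV with a `guide_id` key column; round-trips bit-exactly.
#'
#' @param counts Integer matrix, guides x samples.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts` returns the integer matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$guide_id
  m
}

#' Write a counting report as JSON
#'
#' @param report The `report` element returned by [count_guides()].
#' @param path Output path.
#' @export
write_count_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
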