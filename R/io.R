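## Tab-separated UTF-8 readers/writers with strict validation. All tables use
## a header row, decimal points, densities in g/ml to >= 4 decimals. Fraction
## index 1 is the densest (first collected from the tube bottom).

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_nsip("nsip_format_error", "%s: missing required column(s): %s",
              what, paste(miss, collapse = ", "))
}

.as_num <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(out)))
    stop_nsip("nsip_format_error", "%s: non-numeric value in column '%s'",
              what, col)
  if (anyNA(out))
    stop_nsip("nsip_format_error", "%s: missing value in column '%s'",
              what, col)
  out
}

.read_tsv <- function(path) {
  if (!file.exists(path))
    stop_nsip("nsip_io_error", "file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             check.names = FALSE, fileEncoding = "UTF-8")
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_nsip("nsip_io_error", "cannot write to '%s'", path)
  invisible(path)
}

#' Read gradient fraction tables
#'
#' Reads the per-fraction table of a set of CsCl gradients: one row per
#' (gradient, fraction) with the measured density, the bulk DNA mass, and
#' the treatment metadata of the gradient. Fractions are validated (unique,
#' contiguous indices from 1; positive densities; non-negative DNA) and
#' returned sorted by index within gradient. Fraction 1 is expected to be
#' the densest; if densities increase monotonically with index the file is
#' rejected, and a warning is issued when they are not monotone.
#'
#' @param path Path to a tab-separated file with columns `gradient_id`,
#'   `fraction`, `density_g_ml`, `dna_ng`, `substrate`, `label`,
#'   `light_level`.
#' @return Data frame with those columns, typed and sorted.
#' @export
read_fractions <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("gradient_id", "fraction", "density_g_ml", "dna_ng",
                      "substrate", "label", "light_level"), "fractions")
  df$fraction <- as.integer(.as_num(df$fraction, "fraction", "fractions"))
  df$density_g_ml <- .as_num(df$density_g_ml, "density_g_ml", "fractions")
  df$dna_ng <- .as_num(df$dna_ng, "dna_ng", "fractions")
  df$light_level <- as.character(df$light_level)
  if (anyDuplicated(df[c("gradient_id", "fraction")]))
    stop_nsip("nsip_format_error",
              "fractions: duplicate (gradient_id, fraction) rows")
  bad <- setdiff(unique(df$substrate), .SUBSTRATES)
  if (length(bad))
    stop_nsip("nsip_vocabulary_error", "fractions: unknown substrate '%s'",
              paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$label), .LABELS)
  if (length(bad))
    stop_nsip("nsip_vocabulary_error", "fractions: unknown label '%s'",
              paste(bad, collapse = ", "))
  if (any(df$density_g_ml <= 0))
    stop_nsip("nsip_format_error", "fractions: densities must be positive")
  if (any(df$dna_ng < 0))
    stop_nsip("nsip_format_error", "fractions: dna_ng must be >= 0")
  df <- df[order(df$gradient_id, df$fraction), , drop = FALSE]
  for (gid in unique(df$gradient_id)) {
    g <- df[df$gradient_id == gid, ]
    if (!identical(g$fraction, seq_len(nrow(g))))
      stop_nsip("nsip_format_error",
                "fractions: gradient '%s' indices not contiguous from 1", gid)
    d <- g$density_g_ml
    if (nrow(g) > 1) {
      if (all(diff(d) > 0))
        stop_nsip("nsip_format_error",
                  "fractions: gradient '%s' densities increase with index; fraction 1 must be densest",
                  gid)
      if (!all(diff(d) < 0))
        warning(sprintf("gradient '%s': densities not strictly decreasing with fraction index", gid))
    }
  }
  rownames(df) <- NULL
  df
}

#' Read an OTU read-count table
#'
#' Long-format counts per (gradient, OTU, fraction). Every fraction index
#' must exist in the already-loaded fraction table; missing (OTU, fraction)
#' pairs are zero-filled; duplicated rows are rejected rather than summed.
#'
#' @param path Tab-separated file with columns `gradient_id`, `otu_id`,
#'   `fraction`, `reads`.
#' @param fractions Fraction table from [read_fractions()].
#' @return Long data frame (`gradient_id`, `otu_id`, `fraction`, `reads`)
#'   zero-filled over every OTU x fraction combination of each gradient.
#' @export
read_counts <- function(path, fractions) {
  df <- .read_tsv(path)
  .require_cols(df, c("gradient_id", "otu_id", "fraction", "reads"), "counts")
  if (nrow(df)) {
    df$fraction <- as.integer(.as_num(df$fraction, "fraction", "counts"))
    reads <- .as_num(df$reads, "reads", "counts")
    if (any(reads < 0))
      stop_nsip("nsip_format_error", "counts: negative read counts")
    if (any(reads %% 1 != 0))
      stop_nsip("nsip_format_error", "counts: non-integer read counts")
    df$reads <- as.integer(reads)
    if (anyDuplicated(df[c("gradient_id", "otu_id", "fraction")]))
      stop_nsip("nsip_reference_error",
                "counts: duplicated (gradient_id, otu_id, fraction) rows")
    known <- paste(fractions$gradient_id, fractions$fraction)
    bad <- !(paste(df$gradient_id, df$fraction) %in% known)
    if (any(bad))
      stop_nsip("nsip_reference_error",
                "counts: %d row(s) reference fractions absent from the gradient table",
                sum(bad))
  } else {
    df <- data.frame(gradient_id = character(), otu_id = character(),
                     fraction = integer(), reads = integer())
  }
  otus <- sort(unique(df$otu_id))
  out <- list()
  for (gid in unique(fractions$gradient_id)) {
    fr <- fractions$fraction[fractions$gradient_id == gid]
    grid <- expand.grid(otu_id = otus, fraction = fr,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (!nrow(grid)) next
    grid$gradient_id <- gid
    sub <- df[df$gradient_id == gid, ]
    key <- paste(sub$otu_id, sub$fraction)
    m <- match(paste(grid$otu_id, grid$fraction), key)
    grid$reads <- ifelse(is.na(m), 0L, sub$reads[m])
    out[[gid]] <- grid[c("gradient_id", "otu_id", "fraction", "reads")]
  }
  if (!length(out))
    return(data.frame(gradient_id = character(), otu_id = character(),
                      fraction = integer(), reads = integer()))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$reads <- as.integer(res$reads)
  res
}

#' Read the OTU taxonomy table
#'
#' @param path Tab-separated file with columns `otu_id`, `domain_flag`
#'   (`"prokaryote"` or `"eukaryote_chloroplast"`) and optionally `taxonomy`.
#' @return Data frame with `otu_id`, `domain_flag` (+ `taxonomy` if present).
#' @export
read_otus <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("otu_id", "domain_flag"), "otus")
  if (anyDuplicated(df$otu_id))
    stop_nsip("nsip_format_error", "otus: duplicated otu_id")
  bad <- setdiff(unique(df$domain_flag), .DOMAINS)
  if (length(bad))
    stop_nsip("nsip_vocabulary_error", "otus: unknown domain_flag '%s'",
              paste(bad, collapse = ", "))
  df
}

#' Read tracer uptake observations
#'
#' @param path Tab-separated file with columns `depth`, `light_level`,
#'   `substrate`, `pn_conc`, `atom_pct_t0`, `atom_pct_tf`, `ambient_conc`,
#'   `spike_conc`, `spike_atom_pct`, `duration`.
#' @return Validated data frame (durations positive, atom% in \[0, 100\],
#'   spike enrichment above the initial particulate atom%).
#' @export
read_uptake <- function(path) {
  df <- .read_tsv(path)
  cols <- c("depth", "light_level", "substrate", "pn_conc", "atom_pct_t0",
            "atom_pct_tf", "ambient_conc", "spike_conc", "spike_atom_pct",
            "duration")
  .require_cols(df, cols, "uptake")
  for (cc in setdiff(cols, c("light_level", "substrate")))
    df[[cc]] <- .as_num(df[[cc]], cc, "uptake")
  bad <- setdiff(unique(df$substrate), .SUBSTRATES)
  if (length(bad))
    stop_nsip("nsip_vocabulary_error", "uptake: unknown substrate '%s'",
              paste(bad, collapse = ", "))
  if (any(df$duration <= 0))
    stop_nsip("nsip_format_error", "uptake: duration must be positive")
  ap <- c(df$atom_pct_t0, df$atom_pct_tf, df$spike_atom_pct)
  if (any(ap < 0 | ap > 100))
    stop_nsip("nsip_format_error", "uptake: atom%% values must lie in [0, 100]")
  if (any(df$spike_atom_pct <= df$atom_pct_t0))
    stop_nsip("nsip_format_error",
              "uptake: spike_atom_pct must exceed atom_pct_t0")
  df
}

#' Write pipeline tables
#'
#' `write_fractions()`, `write_counts()`, `write_otus()`, `write_uptake()`
#' and `write_truth()` emit the tab-separated inputs the corresponding
#' readers consume; `write_enrichment()`, `write_budget()` and
#' `write_summary()` emit analysis outputs with a stable column order and
#' floats at 6 significant digits.
#'
#' @param x Data frame (or [sip_enrich()] / [n_budget()] object for the
#'   result writers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_fractions <- function(x, path) .write_tsv(
  x[c("gradient_id", "fraction", "density_g_ml", "dna_ng", "substrate",
      "label", "light_level")], path, digits = 15)

#' @rdname write_tables
#' @export
write_counts <- function(x, path) .write_tsv(
  x[c("gradient_id", "otu_id", "fraction", "reads")], path)

#' @rdname write_tables
#' @export
write_otus <- function(x, path) .write_tsv(x, path)

#' @rdname write_tables
#' @export
write_uptake <- function(x, path) .write_tsv(x, path, digits = 15)

#' @rdname write_tables
#' @export
write_truth <- function(x, path) .write_tsv(x, path)

.ENRICH_COLS <- c("otu_id", "substrate", "light_level", "control_density",
                  "labeled_density", "shift", "t_stat", "df", "p_value",
                  "q_value", "percent_enrichment", "enriched", "excluded",
                  "exclude_reason", "total_reads_labeled",
                  "total_reads_control")

#' @rdname write_tables
#' @export
write_enrichment <- function(x, path) {
  if (inherits(x, "sip_enrichment")) x <- x$results
  if (is.null(x))
    stop_nsip("nsip_input_error", "results must not be NULL")
  if (!nrow(x)) {
    x <- as.data.frame(setNames(rep(list(logical(0)), length(.ENRICH_COLS)),
                                .ENRICH_COLS))
  }
  .write_tsv(x[.ENRICH_COLS], path)
}

#' @rdname write_tables
#' @export
write_budget <- function(x, path) {
  if (inherits(x, "n_budget")) x <- x$table
  if (is.null(x))
    stop_nsip("nsip_input_error", "budget must not be NULL")
  .write_tsv(x[c("substrate", "integrated_rate", "fraction_of_total",
                 "c_equivalent")], path)
}

#' @rdname write_tables
#' @export
write_summary <- function(x, path) {
  if (inherits(x, "sip_activity")) x <- x$by_treatment
  .write_tsv(x, path)
}
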