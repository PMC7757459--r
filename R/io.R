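#' @importFrom data.table fread fwrite as.data.table setDF :=
#' @importFrom stats median mad sd cor pt qbeta pbinom prcomp t.test p.adjust
#'   var rnorm runif setNames uniroot
#' @importFrom utils head
NULL

TC_COLUMNS <- c("sample_id", "peptide_id", "replicate_id", "cycle",
                "foreground", "background")
META_COLUMNS <- c("sample_id", "cohort_id", "batch_id", "therapy",
                  "anticoagulant", "bor", "sd_duration_days", "pfs_days",
                  "progressed")

#' Read a long-format spot time-course table
#'
#' One row per (sample, peptide, replicate, cycle) with foreground and local
#' background fluorescence in arbitrary units. The kinetic time axis is the
#' pump cycle index of the porous-array read-out.
#'
#' @param path CSV file with header
#'   `sample_id,peptide_id,replicate_id,cycle,foreground,background`.
#' @return A `data.frame` with those six columns, validated.
#' @export
read_timecourses <- function(path) {
  tc <- setDF(fread(path, sep = ",", header = TRUE, colClasses = list(
    character = c("sample_id", "peptide_id"))))
  validate_timecourses(tc)
}

#' Write a spot time-course table
#'
#' Inverse of [read_timecourses()]: round-trips up to row order.
#'
#' @param tc validated time-course `data.frame`.
#' @param path output CSV path.
#' @export
write_timecourses <- function(tc, path) {
  tc <- validate_timecourses(tc)
  fwrite(tc[TC_COLUMNS], path, sep = ",")
  invisible(path)
}

#' Validate a time-course table
#'
#' Checks header, numeric intensities, and uniqueness of the
#' (sample, peptide, replicate, cycle) key; errors carry the offending
#' column or key.
#'
#' @param tc candidate `data.frame`.
#' @return the validated `data.frame` (columns reordered to the canonical
#'   header).
#' @export
validate_timecourses <- function(tc) {
  missing <- setdiff(TC_COLUMNS, names(tc))
  if (length(missing))
    stop("time-course table is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("cycle", "foreground", "background")) {
    v <- tc[[col]]
    if (!is.numeric(v))
      stop("time-course column '", col, "' is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("time-course column '", col, "' has non-finite value(s), e.g. row ",
           bad[1])
  }
  key <- paste(tc$sample_id, tc$peptide_id, tc$replicate_id, tc$cycle,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    parts <- strsplit(key[dup[1]], "\r", fixed = TRUE)[[1]]
    stop("duplicate (sample, peptide, replicate, cycle) key: (",
         paste(parts, collapse = ", "), ") at row ", dup[1])
  }
  tc[TC_COLUMNS]
}

#' Read per-sample clinical metadata
#'
#' @param path CSV with header `sample_id,cohort_id,batch_id,therapy,`
#'   `anticoagulant,bor,sd_duration_days,pfs_days,progressed`. Empty fields
#'   are read as missing.
#' @return `data.frame` with one row per sample.
#' @export
read_sample_meta <- function(path) {
  meta <- setDF(fread(path, sep = ",", header = TRUE, na.strings = c("", "NA"),
                      colClasses = list(character = "sample_id")))
  missing <- setdiff(META_COLUMNS, names(meta))
  if (length(missing))
    stop("metadata table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  meta
}

#' Write per-sample clinical metadata
#' @param meta metadata `data.frame`.
#' @param path output CSV path.
#' @export
write_sample_meta <- function(meta, path) {
  fwrite(meta[intersect(c(META_COLUMNS, "label"), names(meta))], path,
         sep = ",")
  invisible(path)
}

#' Derive the binary clinical-benefit label for one sample
#'
#' Two labeling schemes are supported. `"bor"` follows RECIST best overall
#' response: CR or PR is a responder; SD counts as clinical benefit only when
#' it lasted at least 90 days (inclusive); PD is a non-responder. SD shorter
#' than 90 days is labeled non-responder by convention. `"pfs140"` groups by
#' progression-free survival: progression within 140 days (inclusive) is a
#' non-responder, later or no progression a responder.
#'
#' Missing required fields yield `"undefined"`, never an error, so cohorts
#' with incomplete clinical data can still be loaded and filtered.
#'
#' @param bor one of `"CR","PR","SD","PD"` or `NA`.
#' @param sd_duration_days duration of stable disease in days (needed when
#'   `bor == "SD"`).
#' @param pfs_days progression-free survival in days.
#' @param progressed logical; whether progression was observed.
#' @param scheme `"bor"` (default) or `"pfs140"`.
#' @return `"responder"`, `"nonresponder"` or `"undefined"`.
#' @export
assign_response_label <- function(bor = NA, sd_duration_days = NA,
                                  pfs_days = NA, progressed = NA,
                                  scheme = c("bor", "pfs140")) {
  scheme <- match.arg(scheme)
  if (scheme == "bor") {
    if (is.na(bor)) return("undefined")
    if (bor %in% c("CR", "PR")) return("responder")
    if (bor == "PD") return("nonresponder")
    if (bor == "SD") {
      if (is.na(sd_duration_days)) return("undefined")
      return(if (sd_duration_days >= 90) "responder" else "nonresponder")
    }
    return("undefined")
  }
  # pfs140
  if (is.na(progressed)) return("undefined")
  if (!progressed) return("responder")
  if (is.na(pfs_days)) return("undefined")
  if (pfs_days <= 140) "nonresponder" else "responder"
}

#' Label every sample of a metadata table
#'
#' @param meta metadata `data.frame`.
#' @param scheme see [assign_response_label()].
#' @return `meta` with a `label` column added (or overwritten).
#' @export
label_samples <- function(meta, scheme = c("bor", "pfs140")) {
  scheme <- match.arg(scheme)
  meta$label <- vapply(seq_len(nrow(meta)), function(i) {
    assign_response_label(bor = meta$bor[i],
                          sd_duration_days = meta$sd_duration_days[i],
                          pfs_days = meta$pfs_days[i],
                          progressed = meta$progressed[i],
                          scheme = scheme)
  }, character(1))
  meta
}

#' Construct an activity matrix
#'
#' The central container downstream of replicate averaging: a samples x
#' peptides numeric matrix with a transform tag (`raw`, `log2` or `vsn`) and
#' a free-text provenance log accumulated by each processing stage.
#'
#' @param values numeric matrix, rownames = sample ids, colnames = peptide
#'   ids.
#' @param transform_tag one of `"raw"`, `"log2"`, `"vsn"`.
#' @param provenance character vector of processing-log lines.
#' @return an `activity_matrix` object (a matrix with attributes).
#' @export
activity_matrix <- function(values, transform_tag = "raw",
                            provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("activity matrix values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("activity matrix needs sample rownames and peptide colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in activity matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate peptide ids in activity matrix")
  if (anyNA(values))
    stop("activity matrix must be complete after replicate averaging")
  transform_tag <- match.arg(transform_tag, c("raw", "log2", "vsn"))
  structure(values, transform_tag = transform_tag,
            provenance = as.character(provenance),
            class = c("activity_matrix", "matrix", "array"))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d samples x %d peptides [%s]\n",
              nrow(x), ncol(x), attr(x, "transform_tag")))
  prov <- attr(x, "provenance")
  if (length(prov)) cat(paste0("  - ", prov, collapse = "\n"), "\n")
  invisible(x)
}

am_annotate <- function(mat, values = NULL, tag = NULL, note = NULL) {
  v <- if (is.null(values)) unclass(mat) else values
  activity_matrix(v,
                  transform_tag = if (is.null(tag)) attr(mat, "transform_tag") else tag,
                  provenance = c(attr(mat, "provenance"), note))
}

#' Write / read an activity matrix as TSV
#'
#' First column `sample_id`, remaining columns one per peptide. The transform
#' tag travels in a `# transform:` comment line.
#'
#' @param mat `activity_matrix`.
#' @param path output TSV path.
#' @export
write_activity_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transform: ", attr(mat, "transform_tag")), con)
  df <- data.frame(sample_id = rownames(mat), unclass(mat),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_matrix
#' @param path TSV path written by [write_activity_matrix()].
#' @export
read_activity_matrix <- function(path) {
  first <- readLines(path, n = 1)
  tag <- if (startsWith(first, "# transform:"))
    trimws(sub("# transform:", "", first, fixed = TRUE)) else "raw"
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  activity_matrix(values, transform_tag = tag)
}

#' @importFrom utils write.table read.table
NULL
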