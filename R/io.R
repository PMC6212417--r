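## Readers and writers for the plain-text interchange formats: TSV matrices
## (first column = feature ID, header = sample IDs), GMT gene sets, survival
## and mutation tables, flat key=value configs.

#' Read a feature-by-sample expression matrix from TSV
#'
#' First column holds feature IDs, the header row holds sample IDs.  Duplicate
#' IDs, missing values and non-numeric cells are load-time errors: downstream
#' regression assumes a complete matrix.
#'
#' @param path TSV file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, paste0("no sample columns in ", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    miract_error(paste0("duplicate feature ID in ", path, ": ",
                        ids[duplicated(ids)][1]))
  }
  if (anyDuplicated(colnames(df)[-1])) {
    miract_error(paste0("duplicate sample ID in ", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) miract_error(paste0("non-numeric cells in ", path))
  if (anyNA(m)) miract_error(paste0("missing values in ", path))
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the feature-ID column.
#' @export
write_expression_tsv <- function(mat, path, id_col = "id") {
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format_num(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' An empty file is a valid empty collection.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    miract_error(paste0("duplicate set name in ", path, ": ",
                        nms[duplicated(nms)][1]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table (sample_id, time, event)
#' @param path TSV path with columns `sample_id`, `time`, `event`.
#' @return data.frame with those columns.
#' @export
read_survival_tsv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  assert_that(all(need %in% colnames(df)),
              paste0("survival table needs columns: ", paste(need, collapse = ", ")))
  df <- df[, need]
  assert_that(!anyNA(df), "missing values in survival table")
  assert_that(all(df$time >= 0), "negative survival time")
  assert_that(all(df$event %in% c(0, 1)), "event must be 0/1")
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample in survival table")
  df
}

#' @rdname read_survival_tsv
#' @param survival data.frame with columns `sample_id`, `time`, `event`.
#' @export
write_survival_tsv <- function(survival, path) {
  lines <- c("sample_id\ttime\tevent",
             paste(survival$sample_id, format_num(survival$time),
                   survival$event, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary mutation table (genes x samples of 0/1)
#' @param path TSV path.
#' @return integer matrix of 0/1.
#' @export
read_mutations_tsv <- function(path) {
  m <- read_expression_tsv(path)
  assert_that(all(m %in% c(0, 1)), "mutation table must be 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Read subtype centroids (gene, classI..classIV) from TSV
#' @param path TSV path with columns `gene`, `classI`, `classII`, `classIII`, `classIV`.
#' @return object as returned by [build_centroids()].
#' @export
read_centroids_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "classI", "classII", "classIII", "classIV")
  assert_that(all(need %in% colnames(df)),
              paste0("centroid table needs columns: ", paste(need, collapse = ", ")))
  m <- as.matrix(df[, need[-1]])
  rownames(m) <- df$gene
  colnames(m) <- c("I", "II", "III", "IV")
  assert_that(!anyDuplicated(df$gene), "duplicate gene in centroid table")
  assert_that(all(is.finite(m)), "non-finite centroid value")
  structure(list(signature_genes = df$gene, centroids = m),
            class = "miract_centroids")
}

#' @rdname read_centroids_tsv
#' @param centroids a `miract_centroids` object.
#' @export
write_centroids_tsv <- function(centroids, path) {
  m <- centroids$centroids
  lines <- c("gene\tclassI\tclassII\tclassIII\tclassIV",
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene signature (gene, value) from TSV
#' @param path TSV path with columns `gene`, `value`.
#' @return data.frame with columns `gene`, `value`.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "value") %in% colnames(df)),
              "signature table needs columns gene, value")
  assert_that(!anyDuplicated(df$gene), "duplicate gene in signature table")
  df[, c("gene", "value")]
}

#' @rdname read_signature_tsv
#' @param signature data.frame with columns `gene`, `value`.
#' @export
write_signature_tsv <- function(signature, path) {
  writeLines(c("gene\tvalue",
               paste(signature$gene, format_num(signature$value), sep = "\t")),
             path)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers become numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_kv_config <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    assert_that(length(m) == 3, paste0("cannot parse config line: ", ln))
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Cross-file input diagnostics
#'
#' Checks sample-ID agreement (including order) between the mRNA and miRNA
#' matrices, duplicated IDs, missing values, and survival-table consistency.
#'
#' @param mrna_path path to the mRNA matrix TSV (required).
#' @param mirna_path optional path to the miRNA matrix TSV.
#' @param survival_path optional path to the survival TSV.
#' @return data.frame with columns `level` ("fatal"/"warning"), `message`;
#'   zero rows when the inputs are clean.
#' @export
validate_inputs <- function(mrna_path, mirna_path = NULL, survival_path = NULL) {
  diags <- data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE)
  add <- function(level, msg) {
    rbind(diags, data.frame(level = level, message = msg,
                            stringsAsFactors = FALSE))
  }
  mrna <- tryCatch(read_expression_tsv(mrna_path), error = function(e) e)
  if (inherits(mrna, "error")) return(add("fatal", conditionMessage(mrna)))
  if (!is.null(mirna_path)) {
    mirna <- tryCatch(read_expression_tsv(mirna_path), error = function(e) e)
    if (inherits(mirna, "error")) {
      diags <- add("fatal", conditionMessage(mirna))
    } else if (!identical(colnames(mrna), colnames(mirna))) {
      bad <- which(colnames(mrna) != colnames(mirna)[seq_len(ncol(mrna))])[1]
      id <- if (ncol(mrna) != ncol(mirna)) {
        "sample counts differ"
      } else {
        paste0("first offending ID: ", colnames(mrna)[bad])
      }
      diags <- add("fatal", paste0("sample IDs disagree between mRNA and miRNA matrices (", id, ")"))
    }
  }
  if (!is.null(survival_path)) {
    surv <- tryCatch(read_survival_tsv(survival_path), error = function(e) e)
    if (inherits(surv, "error")) {
      diags <- add("fatal", conditionMessage(surv))
    } else {
      missing <- setdiff(surv$sample_id, colnames(mrna))
      if (length(missing) > 0) {
        diags <- add("warning",
                     paste0(length(missing), " survival samples absent from the expression matrix"))
      }
    }
  }
  diags
}
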