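#' Read a normalized log2 expression matrix
#'
#' Expects a tab-delimited file: first column probe-set ids, header row of
#' sample ids, numeric log2 intensities. Row and column order are preserved.
#'
#' @param path file path.
#' @return numeric matrix (probes x samples) with unique dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a probe-id column and >=1 sample")
  probe_ids <- as.character(df[[1]])
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(df)[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric value(s) in expression matrix")
  if (any(!is.finite(vals))) stop("missing or non-finite value(s) in expression matrix")
  dimnames(vals) <- list(probe_ids, sample_ids)
  vals
}

#' Write an expression matrix as tab-delimited text
#'
#' Full printed precision (17 significant digits) so that write-then-read
#' round-trips bit-exactly.
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(probe_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default mapping from file class labels to the three analysis roles
#'
#' Real sample sheets label septic groups by the surgical model (CLP, CS);
#' the analyses only care about three roles: control, modelA, modelB.
#' @export
default_class_map <- function() {
  c(control = "control", Control = "control", healthy = "control",
    modelA = "modelA", CLP = "modelA",
    modelB = "modelB", CS = "modelB")
}

#' Read and validate the sample annotation sheet
#'
#' @param path CSV (or TSV) with columns `sample_id`, `class_label`,
#'   `timepoint` (empty/NA for controls).
#' @param class_map named character vector mapping file labels to
#'   control/modelA/modelB; defaults to [default_class_map()].
#' @param expr optional expression matrix to align against: every matrix
#'   sample must appear exactly once.
#' @return data.frame with `sample_id`, `class_label`, `timepoint`.
#' @export
read_sample_annotation <- function(path, class_map = default_class_map(),
                                   expr = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "class_label", "timepoint")
  if (!all(need %in% colnames(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  unknown <- setdiff(unique(df$class_label), names(class_map))
  if (length(unknown)) stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  df$class_label <- unname(class_map[df$class_label])
  bad <- df$class_label == "control" & !is.na(df$timepoint)
  if (any(bad)) {
    stop("control sample(s) carry a timepoint: ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  bad <- df$class_label != "control" & is.na(df$timepoint)
  if (any(bad)) {
    stop("septic sample(s) missing a timepoint: ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(expr)) align_samples(expr, df)
  df
}

align_samples <- function(expr, samples) {
  missing <- setdiff(colnames(expr), samples$sample_id)
  if (length(missing)) {
    stop("matrix sample(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read the probe-set to gene-symbol annotation
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`. A gene symbol may
#'   be shared by several probe ids; probes without a symbol (empty cell) are
#'   kept with `NA` and excluded from gene-level collapsing downstream.
#' @param expr optional matrix to align against: every matrix probe must have
#'   exactly one annotation row.
#' @return data.frame with `probe_id`, `gene_symbol`.
#' @export
read_probe_annotation <- function(path, expr = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% colnames(df))) {
    stop("probe annotation must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(expr)) {
    missing <- setdiff(rownames(expr), df$probe_id)
    if (length(missing)) {
      stop("matrix probe(s) absent from annotation: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  n_unannot <- sum(is.na(df$gene_symbol))
  if (n_unannot > 0) {
    message(n_unannot, " probe set(s) lack a gene symbol; they are retained ",
            "for probe-level statistics and skipped in gene collapsing")
  }
  df
}

#' Read gene sets in GMT format, with an optional direction suffix
#'
#' Each line is `name<TAB>description<TAB>member...`. A member may carry an
#' expected regulation direction as `SYMBOL|+1` (up) or `SYMBOL|-1` (down);
#' if any member of a set has a suffix, all must.
#'
#' @param path GMT file path.
#' @return named list of gene sets; each is a list with `name`, `genes`
#'   (character) and `directions` (named +1/-1 vector, or NULL).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("gene set line has no members: ", substr(line, 1, 40))
    }
    name <- parts[1]
    members <- parts[-(1:2)]
    has_dir <- grepl("|", members, fixed = TRUE)
    if (any(has_dir) && !all(has_dir)) {
      stop("set ", name, ": direction suffixes must cover all genes or none")
    }
    if (all(has_dir)) {
      split_m <- strsplit(members, "|", fixed = TRUE)
      genes <- vapply(split_m, `[`, "", 1)
      dirs <- vapply(split_m, function(p) {
        if (length(p) != 2 || !p[2] %in% c("+1", "-1", "1")) {
          stop("set ", name, ": malformed direction suffix '",
               paste(p, collapse = "|"), "'")
        }
        as.numeric(p[2])
      }, 0)
      names(dirs) <- genes
    } else {
      genes <- members
      dirs <- NULL
    }
    dup <- genes[duplicated(genes)]
    if (length(dup)) {
      stop("set ", name, ": duplicated gene(s): ", paste(unique(dup), collapse = ", "))
    }
    list(name = name, genes = genes, directions = dirs)
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets in the GMT dialect read by [read_gene_sets()]
#' @param sets list of gene sets (as returned by [read_gene_sets()]).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    members <- if (is.null(s$directions)) s$genes else {
      paste0(s$genes, "|", ifelse(s$directions[s$genes] > 0, "+1", "-1"))
    }
    paste(c(s$name, "na", members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
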