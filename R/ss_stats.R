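SS_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "P", "C")

#' Parse per-residue secondary-structure labels
#'
#' Reads secondary-structure assignments from the text output of DSSP
#' (classic `mkdssp` and DSSP 4 layouts, which add the polyproline-II
#' category P), from STRIDE output (`ASG` records), or from a plain
#' three-column TSV (`chain`, `resnum`, `label`).  Blank / unassigned
#' labels map to the coil category C, so every residue carries one of the
#' nine letters H, G, I, E, B, T, S, P, C.
#'
#' @param path Path to the label file.
#' @param dialect One of `"tsv"`, `"dssp"`, `"stride"`.
#' @return A data frame of class `ss_labels` with columns `chain`, `resno`,
#'   `label` and attribute `source` (the dialect).
#' @export
parse_labels <- function(path, dialect = c("tsv", "dssp", "stride")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- switch(dialect,
    tsv = {
      df <- read.table(path, sep = "\t", header = TRUE,
                       colClasses = c("character", "integer", "character"),
                       na.strings = NULL, quote = "")
      names(df) <- c("chain", "resno", "label")
      df$label <- trimws(df$label)
      df$label[df$label == ""] <- "C"
      df
    },
    dssp = {
      hdr <- grep("^  #  RESIDUE", lines)
      if (length(hdr) == 0L) stop("not a DSSP output file: ", path)
      body <- lines[(hdr[1L] + 1L):length(lines)]
      body <- body[nchar(body) >= 17]
      # chain-break separator rows carry '!' in the AA column (14)
      body <- body[substr(body, 14, 14) != "!"]
      resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
      keep <- !is.na(resno)
      body <- body[keep]
      lab <- substr(body, 17, 17)
      lab[lab == " "] <- "C"
      data.frame(chain = trimws(substr(body, 12, 12)),
                 resno = resno[keep], label = lab,
                 stringsAsFactors = FALSE)
    },
    stride = {
      asg <- lines[startsWith(lines, "ASG")]
      if (length(asg) == 0L) stop("no ASG records found in ", path)
      parts <- strsplit(trimws(asg), "[[:space:]]+")
      data.frame(chain = vapply(parts, `[`, "", 3L),
                 resno = as.integer(vapply(parts, `[`, "", 4L)),
                 label = toupper(vapply(parts, `[`, "", 6L)),
                 stringsAsFactors = FALSE)
    })
  bad <- setdiff(unique(out$label), SS_ALPHABET)
  if (length(bad)) {
    stop("unknown secondary-structure label(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(out[c("chain", "resno")])) {
    stop("duplicate residue entries in ", path)
  }
  class(out) <- c("ss_labels", "data.frame")
  attr(out, "source") <- dialect
  out
}

#' Per-category folding-degree statistics
#'
#' Joins a secondary-structure labelling with a residue folding-degree
#' profile and summarises the folding degree per category: count, mean,
#' sample (n-1) standard deviation, and quartiles.  Residues without a
#' defined folding degree (stretch termini, incomplete backbones) are
#' excluded; categories with a single residue report `NA` for the standard
#' deviation.
#'
#' @param labels An `ss_labels` data frame (see [parse_labels()]).
#' @param profile A `folding_profile` (see [rcs_profile()]).
#' @return A data frame with one row per observed category: `category`,
#'   `count`, `mean`, `sd`, `q1`, `median`, `q3`.
#' @export
category_stats <- function(labels, profile) {
  key_l <- paste(labels$chain, labels$resno)
  key_p <- paste(profile$chain, profile$resno)
  idx <- match(key_l, key_p)
  rcs <- profile$rcs[idx]
  ok <- !is.na(idx) & !is.na(rcs)
  if (!any(ok)) stop("no residues with both a label and a defined RCS")
  lab <- labels$label[ok]
  rcs <- rcs[ok]
  cats <- intersect(SS_ALPHABET, unique(lab))
  rows <- lapply(cats, function(cc) {
    v <- rcs[lab == cc]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = cc, count = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               q1 = q[1L], median = q[2L], q3 = q[3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between two secondary-structure labelings
#'
#' Cross-tabulates two labelings of the same residues (e.g. DSSP 4 versus
#' STRIDE) into a 9x9 confusion matrix and reports the percentage of
#' residues of each reference category that the second labelling assigns
#' elsewhere.
#'
#' @param labels_a Reference labelling (`ss_labels`).
#' @param labels_b Comparison labelling over the same residues.
#' @return A list of class `ss_agreement`: `confusion` (9x9 count matrix,
#'   rows = reference categories) and `disagreement_pct` (named vector, NA
#'   for categories absent from the reference).
#' @export
agreement_matrix <- function(labels_a, labels_b) {
  key_a <- paste(labels_a$chain, labels_a$resno)
  key_b <- paste(labels_b$chain, labels_b$resno)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b)) {
    stop("the two labelings cover different residue sets")
  }
  lb <- labels_b$label[match(key_a, key_b)]
  la <- factor(labels_a$label, levels = SS_ALPHABET)
  lb <- factor(lb, levels = SS_ALPHABET)
  conf <- table(reference = la, comparison = lb)
  tot <- rowSums(conf)
  dis <- 100 * (tot - diag(conf)) / tot
  dis[tot == 0] <- NA_real_
  structure(list(confusion = unclass(conf), disagreement_pct = dis),
            class = "ss_agreement")
}

#' @export
print.ss_agreement <- function(x, ...) {
  cat("<ss_agreement> per-category % disagreement:\n")
  print(round(x$disagreement_pct, 2))
  invisible(x)
}

#' Motif-length histograms
#'
#' A motif is a maximal run of residues sharing one secondary-structure
#' category.  Runs never extend across chains; per category the function
#' tabulates how many motifs of each length occur.
#'
#' @param labels An `ss_labels` data frame.
#' @return Named list (by category) of tables mapping run length to count.
#'   Categories that never occur are absent.
#' @export
#' @examples
#' labs <- data.frame(chain = "A", resno = 1:7,
#'                    label = c("H","H","H","H","T","T","E"))
#' motif_lengths(labs)
motif_lengths <- function(labels) {
  if (nrow(labels) == 0L) return(setNames(list(), character(0)))
  out <- list()
  for (ch in unique(labels$chain)) {
    sub <- labels[labels$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    r <- rle(sub$label)
    for (i in seq_along(r$values)) {
      cc <- r$values[i]
      len <- as.character(r$lengths[i])
      if (is.null(out[[cc]])) out[[cc]] <- integer(0)
      out[[cc]][len] <- if (is.na(out[[cc]][len])) 1L
                        else out[[cc]][len] + 1L
    }
  }
  lapply(out, function(v) v[order(as.integer(names(v)))])
}

#' Write category statistics / confusion / run-length outputs
#'
#' @param stats Data frame from [category_stats()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_category_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
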