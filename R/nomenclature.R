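#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Genes covered by the toolkit: classical class I and class II loci.
HLA_GENES <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1", "DRB1")
HLA_CLASS_I <- c("A", "B", "C")
HLA_CLASS_II <- c("DPA1", "DPB1", "DQA1", "DQB1", "DRB1")

# Expression suffixes defined by HLA nomenclature (G marks a G-group name,
# handled separately).
HLA_SUFFIXES <- c("N", "L", "S", "C", "A", "Q")

#' Supported HLA genes
#'
#' @param mhc_class Optional class filter: `"I"` (HLA-A/B/C), `"II"`
#'   (HLA-DPA1/DPB1/DQA1/DQB1/DRB1) or `NULL` for all eight genes.
#' @return Character vector of gene symbols (without the `HLA-` prefix).
#' @export
#' @examples
#' hla_genes("I")
hla_genes <- function(mhc_class = NULL) {
  if (is.null(mhc_class)) return(HLA_GENES)
  mhc_class <- match.arg(as.character(mhc_class), c("I", "II"))
  if (mhc_class == "I") HLA_CLASS_I else HLA_CLASS_II
}

#' MHC class of a gene
#'
#' @param gene Character vector of gene symbols.
#' @return `"I"` or `"II"` for each element.
#' @export
hla_class_of <- function(gene) {
  out <- ifelse(gene %in% HLA_CLASS_I, "I",
                ifelse(gene %in% HLA_CLASS_II, "II", NA_character_))
  if (anyNA(out)) {
    stop("unsupported gene(s): ",
         paste(unique(gene[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Parse HLA allele names
#'
#' Decomposes allele strings such as `"A*01:01:01:01"` or `"HLA-DRB1*14:02"`
#' into gene and colon-separated fields. An optional `HLA-` prefix is
#' stripped and the gene symbol is upper-cased; field text is preserved
#' verbatim so that rendering the result reproduces the canonical name.
#' The final field may carry a trailing expression suffix (N/L/S/C/A/Q) or
#' a `G` marking a G-group name.
#'
#' @param name Character vector of allele names.
#' @return A tibble with one row per input: `allele` (canonical rendering),
#'   `gene`, `fields` (list of character vectors), `n_fields`, `suffix`
#'   (expression letter or `NA`), `is_g_group`.
#' @export
#' @examples
#' hla_parse(c("A*01:01:01:01", "HLA-DRB1*14:02"))
hla_parse <- function(name) {
  stopifnot(is.character(name))
  raw <- sub("^HLA-", "", name)
  star <- regexpr("*", raw, fixed = TRUE)
  bad <- star < 0L
  if (any(bad)) {
    stop("malformed allele name (missing '*'): '", name[which(bad)[1]], "'",
         call. = FALSE)
  }
  gene <- toupper(substr(raw, 1L, star - 1L))
  unknown <- !gene %in% HLA_GENES
  if (any(unknown)) {
    stop("unsupported gene '", gene[which(unknown)[1]], "' in allele '",
         name[which(unknown)[1]], "'", call. = FALSE)
  }
  rest <- substr(raw, star + 1L, nchar(raw))
  fields <- strsplit(rest, ":", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) == 0L || any(!nzchar(f)) || grepl("::", rest[i], fixed = TRUE) ||
        endsWith(rest[i], ":")) {
      stop("malformed allele name (empty field): '", name[i], "'", call. = FALSE)
    }
    last <- f[length(f)]
    tail_letter <- sub("^[0-9]+", "", last)
    head_ok <- grepl("^[0-9]+", last)
    body_ok <- all(grepl("^[0-9]+$", f[-length(f)]))
    if (!head_ok || !body_ok ||
        !(tail_letter == "" || tail_letter %in% c(HLA_SUFFIXES, "G"))) {
      stop("malformed allele field '", last, "' in allele '", name[i], "'",
           call. = FALSE)
    }
  }
  last_field <- vapply(fields, function(f) f[length(f)], character(1))
  letter <- sub("^[0-9]+", "", last_field)
  tibble(
    allele = paste0(gene, "*", vapply(fields, paste, character(1), collapse = ":")),
    gene = gene,
    fields = fields,
    n_fields = lengths(fields),
    suffix = ifelse(letter %in% HLA_SUFFIXES, letter, NA_character_),
    is_g_group = letter == "G"
  )
}

#' Render parsed alleles back to canonical strings
#'
#' @param parsed A tibble as returned by [hla_parse()].
#' @return Character vector of canonical allele names.
#' @export
hla_render <- function(parsed) {
  paste0(parsed$gene, "*",
         vapply(parsed$fields, paste, character(1), collapse = ":"))
}

#' Trim alleles to a given field resolution
#'
#' Keeps at most `n` colon-separated fields ("second-field resolution" for
#' the default `n = 2`). An expression suffix attached to a dropped field is
#' discarded with it. G-group names are atomic comparison units and are
#' returned unchanged: trimming `01:01:01G` would destroy group identity.
#'
#' @param allele Character vector of allele names.
#' @param n Number of fields to keep (>= 1).
#' @return Character vector of trimmed canonical names.
#' @export
#' @examples
#' hla_trim("A*01:01:01:01")   # "A*01:01"
#' hla_trim("A*01:01:01G")     # unchanged
hla_trim <- function(allele, n = 2L) {
  stopifnot(length(n) == 1L, n >= 1L)
  p <- hla_parse(allele)
  keep <- !p$is_g_group & p$n_fields > n
  p$fields[keep] <- lapply(p$fields[keep], function(f) f[seq_len(n)])
  hla_render(p)
}

#' Read an IPD-IMGT G-group mapping file
#'
#' Parses the `hla_nom_g.txt` dialect: `#`-prefixed comments, then data
#' lines `GENE*;member1/member2/...;GROUP` with exactly three `;`-separated
#' fields. Each member allele (prefixed with its gene) maps to
#' `GENE*GROUP`; when the group field is empty the single listed allele
#' maps to itself.
#'
#' @param path Path to the mapping file.
#' @return A tibble with columns `allele` (full member rendering), `group`
#'   (full target rendering) and `gene`, carrying the source path in the
#'   `"provenance"` attribute. Genes outside the supported set are skipped.
#' @export
read_g_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[i]
    n_sep <- nchar(gsub("[^;]", "", line))
    if (n_sep != 2L) {
      stop("G-group file format error at line ", lineno[i],
           ": expected 3 ';'-separated fields, found ", n_sep + 1L,
           call. = FALSE)
    }
    parts <- strsplit(line, ";", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 3L - length(parts)))
    gene_prefix <- parts[1]                       # e.g. "A*"
    gene <- sub("\\*$", "", gene_prefix)
    if (!gene %in% HLA_GENES) next
    members <- strsplit(parts[2], "/", fixed = TRUE)[[1]]
    group <- trimws(parts[3])
    target <- if (nzchar(group)) {
      paste0(gene_prefix, group)
    } else {
      paste0(gene_prefix, members)               # singleton self-mapping
    }
    rows[[i]] <- tibble(
      allele = paste0(gene_prefix, members),
      group = target,
      gene = gene
    )
  }
  tab <- dplyr::bind_rows(rows)
  dup <- tab |>
    dplyr::distinct(.data$allele, .data$group) |>
    dplyr::count(.data$allele) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("G-group consistency error: allele '", dup$allele[1],
         "' assigned to multiple groups", call. = FALSE)
  }
  tab <- dplyr::distinct(tab)
  attr(tab, "provenance") <- path
  tab
}

#' Normalize alleles to G-groups and second-field resolution
#'
#' The comparison unit used throughout the package: an allele listed as a
#' G-group member is replaced by its group name; anything else is trimmed
#' to `n_fields` fields. An allele reported at lower resolution than the
#' table entries maps to a group only when every listed extension of it
#' belongs to that same group; otherwise it falls back to trimming. The
#' rules are applied to a fixed point, which makes the function idempotent.
#'
#' @param allele Character vector of allele names.
#' @param g_groups A mapping tibble from [read_g_groups()], or `NULL` to
#'   trim only.
#' @param n_fields Resolution for the trimming fallback (default 2).
#' @return Character vector of normalized canonical names.
#' @export
#' @examples
#' g <- read_g_groups(system.file("extdata", "hla_nom_g_fixture.txt",
#'                                package = "hlabench"))
#' hla_normalize("A*01:01:01:01", g)  # "A*01:01:01G"
#' hla_normalize("B*57:11:22", g)     # "B*57:11" (not listed: trimmed)
hla_normalize <- function(allele, g_groups = NULL, n_fields = 2L) {
  p <- hla_parse(allele)
  single <- p$n_fields == 1L & !p$is_g_group
  if (any(single)) {
    warning("allele(s) at first-field resolution cannot be normalized ",
            "reliably and are returned trimmed only: ",
            paste(unique(p$allele[single]), collapse = ", "), call. = FALSE)
  }
  vapply(seq_len(nrow(p)), function(i) {
    normalize_one(p$allele[i], g_groups, n_fields)
  }, character(1))
}

# One allele to its fixed point under {group lookup, unique-extension
# lookup, one-step trim}.
normalize_one <- function(a, g_groups, n_fields) {
  repeat {
    pa <- hla_parse(a)
    if (pa$is_g_group[1]) return(a)
    if (!is.null(g_groups)) {
      hit <- g_groups$group[g_groups$allele == a]
      if (length(hit) == 1L) {
        if (hit == a) return(a)
        a <- hit
        next
      }
      if (pa$n_fields[1] > 1L && is.na(pa$suffix[1])) {
        ext <- g_groups$group[startsWith(g_groups$allele, paste0(a, ":"))]
        if (length(ext) > 0L && length(unique(ext)) == 1L) {
          a <- ext[1]
          next
        }
      }
    }
    if (pa$n_fields[1] > n_fields) {
      a <- hla_trim(a, n_fields)
      next
    }
    return(a)
  }
}
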