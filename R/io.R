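#' Read a genetic map from TSV
#'
#' Expected columns `marker`, `chromosome`, `position_cM` (tab-separated,
#' `#`-prefixed metadata lines ignored).  Chromosomes keep their order of
#' first appearance; positions must be strictly increasing within a
#' chromosome and marker names unique genome-wide.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(d)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  genetic_map(d$marker, d$chromosome, d$position_cM)
}

#' Read a marker-genotype matrix from TSV
#'
#' Rows are individuals, columns markers (header = marker names).  Accepted
#' genotype dialects: letters `A`/`B`/`-` or numbers `2`/`0`/`-1`,
#' normalized to `+1` (P1 class), `-1` (P2 class) and `NA`.  Heterozygote
#' codes are illegal in the two-class populations handled here.
#'
#' @param path file path.
#' @param map optional [genetic_map()]; when given, columns are checked and
#'   reordered against the map.
#' @return numeric matrix of +1/-1/NA codes.
#' @export
read_genotypes <- function(path, map = NULL) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  g <- as.matrix(d)
  codes <- sort(unique(as.vector(g[!is.na(g) & g != ""])))
  legal_letters <- c("A", "B", "-")
  legal_numbers <- c("2", "0", "-1")
  out <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  if (all(codes %in% legal_letters)) {
    out[g == "A"] <- 1; out[g == "B"] <- -1
  } else if (all(codes %in% legal_numbers)) {
    out[g == "2"] <- 1; out[g == "0"] <- -1
  } else {
    bad <- setdiff(codes, c(legal_letters, legal_numbers))
    where <- which(matrix(g %in% bad, nrow(g)), arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", bad[1], "' at data row ", where[1],
         ", column ", where[2],
         " (heterozygotes are illegal in DH/BC1/RIL input)")
  }
  if (!is.null(map)) {
    if (!setequal(colnames(out), map$marker))
      stop("genotype columns do not match the map's markers")
    out <- out[, map$marker, drop = FALSE]
  }
  out
}

#' Read a phenotype matrix from TSV
#'
#' Rows are individuals, columns environments; `NA` (or empty) cells allowed.
#'
#' @param path file path.
#' @return numeric matrix with attribute `"n_obs"` (non-missing count per
#'   environment).
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  y <- as.matrix(d)
  storage.mode(y) <- "double"
  attr(y, "n_obs") <- colSums(!is.na(y))
  y
}

write_tsv_meta <- function(d, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write simulator / scan outputs as self-describing TSV
#'
#' All outputs are tab-separated with `#`-prefixed metadata lines carrying
#' the generating configuration, so any result file can be traced to its
#' settings.
#'
#' @param x a `genetic_map`, genotype matrix, phenotype matrix or
#'   `qei_scan` data.frame.
#' @param path output file.
#' @param meta character vector of metadata lines (written as `# ...`).
#' @param dialect genotype letter (`"AB"`) or number (`"numeric"`) coding.
#' @return `path`, invisibly.
#' @export
write_qei <- function(x, path, meta = character(0), dialect = c("AB", "numeric")) {
  dialect <- match.arg(dialect)
  if (inherits(x, "genetic_map")) {
    write_tsv_meta(as.data.frame(x), path, meta)
  } else if (is.matrix(x) && !is.null(colnames(x)) &&
             all(x %in% c(1, -1, NA))) {
    g <- matrix(if (dialect == "AB") "-" else "NA", nrow(x), ncol(x),
                dimnames = dimnames(x))
    if (dialect == "AB") {
      g[which(x == 1)] <- "A"; g[which(x == -1)] <- "B"
    } else {
      g[which(x == 1)] <- "2"; g[which(x == -1)] <- "0"
      g[which(is.na(x))] <- "-1"
    }
    write_tsv_meta(as.data.frame(g, check.names = FALSE), path, meta)
  } else {
    write_tsv_meta(as.data.frame(x), path, meta)
  }
  invisible(path)
}
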