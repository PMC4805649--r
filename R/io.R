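#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect has a header row `marker_id`, `chromosome`, `position`
#' followed by one column per line id, then one row per marker with integer
#' dosages (`NA` for missing).  VCF input (v4.x) keeps biallelic SNP
#' records only; multi-allelic records are skipped with a message giving
#' the count, and dosage is the ALT-allele count of the `GT` field.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [genotypes()] object, markers sorted by (chromosome, position).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 4) stop("genotype TSV needs marker_id, chromosome, position and >=1 line column")
  lines <- names(tab)[-(1:3)]
  dos <- suppressWarnings(
    vapply(seq_len(ncol(tab) - 3),
           function(j) as.numeric(tab[[j + 3]]), numeric(nrow(tab))))
  if (nrow(tab) == 1L) dos <- matrix(dos, nrow = 1L)
  raw <- as.matrix(tab[, -(1:3), drop = FALSE])
  bad <- is.na(dos) & !(raw %in% c("NA", "", "NaN") | is.na(raw))
  if (any(bad)) {
    stop("malformed dosage value at data row ",
         which(rowSums(bad) > 0)[1], " of ", path)
  }
  pos <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(pos)) stop("malformed position at data row ", which(is.na(pos))[1])
  map <- data.frame(marker_id = tab[[1]], chromosome = tab[[2]],
                    position = as.integer(pos))
  genotypes(t(dos), map, lines = lines)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " multi-allelic VCF record(s) skipped")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  })
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = sum(keep), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], "_", fix[miss_id, "POS"])
  map <- data.frame(marker_id = ids, chromosome = fix[, "CHROM"],
                    position = as.integer(fix[, "POS"]))
  genotypes(t(dos), map, lines = colnames(gt))
}

#' Write a genotype matrix in the TSV dialect
#'
#' @param G a [genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  out <- data.frame(marker_id = G$map$marker_id,
                    chromosome = G$map$chromosome,
                    position = G$map$position,
                    t(G$dosage), check.names = FALSE)
  names(out)[-(1:3)] <- G$lines
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' TSV with header columns `line`, `environment`, `replication`, `value`;
#' one row per plot record (days to flowering).  Each
#' (line, environment, replication) key must be unique.
#'
#' @param path file path.
#' @return data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("line", "environment", "replication", "value")
  if (!all(need %in% names(tab))) {
    stop("phenotype TSV must have columns: ", paste(need, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(tab$value))
  bad <- is.na(val) & !(tab$value %in% c("NA", ""))
  if (any(bad)) stop("non-numeric phenotype value at data row ", which(bad)[1])
  rep_ <- suppressWarnings(as.integer(tab$replication))
  if (anyNA(rep_)) stop("non-integer replication at data row ", which(is.na(rep_))[1])
  phenotype_table(data.frame(line = tab$line, environment = tab$environment,
                             replication = rep_, value = val))
}

#' Construct / validate a phenotype table
#'
#' @param records data frame with columns `line`, `environment`,
#'   `replication` (integer >= 1), `value` (positive days).
#' @return the validated data frame with class `phenotype_table`.
#' @export
phenotype_table <- function(records) {
  records <- as.data.frame(records)
  need <- c("line", "environment", "replication", "value")
  stopifnot(all(need %in% names(records)))
  records$line <- as.character(records$line)
  records$environment <- as.character(records$environment)
  records$replication <- as.integer(records$replication)
  if (any(records$replication < 1L, na.rm = TRUE)) stop("replication must be >= 1")
  key <- paste(records$line, records$environment, records$replication, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate phenotype record for (", d$line, ", ", d$environment,
         ", rep ", d$replication, ")")
  }
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' Write a phenotype table as TSV
#' @param pheno a `phenotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno)[, c("line", "environment", "replication", "value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate-gene coordinate table
#'
#' Accepts BED3+ (0-based, half-open, no header: chrom, start, end,
#' optional name) or a headered TSV with 1-based inclusive coordinates
#' (`gene_id`, `chromosome`, `start`, `end`, optional `homolog`).  Internal
#' coordinates are always 1-based inclusive, so a BED start is shifted up
#' by one on input.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @return data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `homolog`.
#' @export
read_gene_table <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(), homolog = character())
  if (format == "bed") {
    if (length(readLines(path, n = 1)) == 0) return(empty)
    tab <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
    if (ncol(tab) < 3) stop("BED needs at least 3 columns")
    nm <- if (ncol(tab) >= 4) tab[[4]] else sprintf("gene%04d", seq_len(nrow(tab)))
    out <- data.frame(gene_id = nm, chromosome = tab[[1]],
                      start = as.integer(tab[[2]]) + 1L,
                      end = as.integer(tab[[3]]),
                      homolog = nm)
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
    if (nrow(tab) == 0) return(empty)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    }
    out <- data.frame(gene_id = tab$gene_id, chromosome = tab$chromosome,
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      homolog = if ("homolog" %in% names(tab)) tab$homolog else tab$gene_id)
  }
  bad <- out$start > out$end
  if (any(bad)) {
    stop("gene interval with start > end after normalization: ", out$gene_id[bad][1])
  }
  out
}

#' Write a gene table (1-based TSV dialect)
#' @param genes gene table data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chromosome", "start", "end", "homolog")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read growth-habit labels
#'
#' TSV with header columns `line` and `growth_type`
#' (`spring`/`winter`/other).
#'
#' @param path file path.
#' @return data frame with columns `line`, `growth_type`.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("line", "growth_type") %in% names(tab))) {
    stop("labels TSV must have columns line, growth_type")
  }
  tab[, c("line", "growth_type")]
}

#' Write growth-habit labels as TSV
#' @param labels data frame with `line`, `growth_type`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(labels[, c("line", "growth_type")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

## normalize labels input (data frame or named vector) to a character
## vector named by line id
growth_labels <- function(labels) {
  if (is.data.frame(labels)) {
    setNames(as.character(labels$growth_type), labels$line)
  } else {
    stopifnot(!is.null(names(labels)))
    setNames(as.character(labels), names(labels))
  }
}
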