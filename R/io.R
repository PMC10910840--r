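#' Read genotype calls from VCF, PLINK-text or TSV
#'
#' All formats produce the same alt-allele-dosage encoding (0/1/2/`NA`).
#' Only biallelic diploid SNP records are supported; multiallelic records
#' are skipped with a message, half-called genotypes (one allele missing)
#' are mapped to missing, and phase separators are accepted and collapsed.
#'
#' Formats:
#' \describe{
#'   \item{vcf}{VCF 4.x text, `GT` genotype field and, when present, the
#'     per-genotype `DP` depth field (read into the call set's depth
#'     matrix).}
#'   \item{plink}{`.ped`/`.map` pair (pass either file or the common
#'     prefix). The `.map` may carry the standard 4 columns (alt allele
#'     then inferred as the minor allele) or 6 columns
#'     (`chrom id cm pos alt ref`), which round-trips allele polarity.}
#'   \item{tsv}{Wide tab-separated table: variant metadata columns
#'     (`id chrom pos ref alt category`) followed by one 0/1/2/NA column
#'     per sample.}
#' }
#'
#' @param path Input file path (for PLINK, the `.ped`, `.map` or prefix).
#' @param format One of `"vcf"`, `"plink"`, `"tsv"`.
#' @param platform Platform tag for the returned [platform_callset]. The
#'   default tags the set `"sequencing"` when per-call depth is available
#'   and `"array"` otherwise.
#' @return A [platform_callset].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("vcf", "plink", "tsv"),
                           platform = NULL) {
  format <- match.arg(format)
  parsed <- switch(format,
    vcf = read_vcf_calls(path),
    plink = read_plink_calls(path),
    tsv = read_tsv_calls(path)
  )
  if (is.null(platform)) {
    platform <- if (is.null(parsed$depth)) "array" else "sequencing"
  }
  if (platform == "array") parsed$depth <- NULL
  platform_callset(parsed$dataset, platform = platform, depth = parsed$depth)
}

#' Write genotype calls to VCF, PLINK-text or TSV
#'
#' Inverse of [read_genotypes()]: a written file re-reads to identical
#' call matrices, ids and alleles.
#'
#' @param dataset A [genotype_dataset] or [platform_callset].
#' @param path Output path (for PLINK, `.ped` path or prefix; the `.map`
#'   is written alongside with 6 columns so polarity round-trips).
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, format = c("vcf", "plink", "tsv")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_vcf_calls(dataset, path),
    plink = write_plink_calls(dataset, path),
    tsv = write_tsv_calls(dataset, path)
  )
  invisible(path)
}

# -- VCF ---------------------------------------------------------------------

gt_to_dosage <- function(gt) {
  # strip any per-genotype subfields beyond the first (GT must be first)
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- !is.na(gt) & gt != "."
  if (!any(known)) return(out)
  alleles <- strsplit(gt[known], "[/|]")
  n_all <- lengths(alleles)
  if (any(n_all != 2)) {
    abort(paste0(
      "unsupported ploidy: genotype '", gt[known][which(n_all != 2)[1]],
      "' is not diploid."
    ))
  }
  out[known] <- vapply(alleles, function(x) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) NA_integer_ else sum(v) # half-calls -> MISSING
  }, integer(1))
  out
}

read_vcf_calls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("VCF parse error in ", path, ": ",
      conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix[, 1:7, drop = FALSE],
    stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    samp <- colnames(v@gt)[-1] %||% character(0)
    ds <- genotype_dataset(
      calls = matrix(integer(0), nrow = length(samp), ncol = 0),
      variants = tibble(
        id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0)
      ),
      samples = tibble(sample_id = samp)
    )
    return(list(dataset = ds, depth = NULL))
  }
  snv <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!snv)) {
    message(sum(!snv), " multiallelic/non-SNV record(s) skipped.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- any(grepl("\\bDP\\b", v@gt[, "FORMAT"]))
  dp <- if (has_dp) {
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  }
  keep <- which(snv)
  if (length(keep) == 0) {
    ds <- genotype_dataset(
      calls = matrix(integer(0), nrow = ncol(gt), ncol = 0),
      variants = tibble(
        id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0)
      ),
      samples = tibble(sample_id = colnames(gt))
    )
    return(list(dataset = ds, depth = NULL))
  }
  calls <- apply(gt[keep, , drop = FALSE], 2, gt_to_dosage)
  calls <- matrix(as.integer(calls),
    nrow = length(keep),
    dimnames = list(NULL, colnames(gt))
  )
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[keep], ":", fix$POS[keep]
  )[is.na(ids) | ids == "."]
  ds <- genotype_dataset(
    calls = t(calls),
    variants = tibble(
      id = ids, chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep], alt = fix$ALT[keep]
    ),
    samples = tibble(sample_id = colnames(gt))
  )
  depth <- if (has_dp) {
    d <- t(dp[keep, , drop = FALSE])
    storage.mode(d) <- "integer"
    dimnames(d) <- dimnames(ds$calls)
    d
  }
  list(dataset = ds, depth = depth)
}

write_vcf_calls <- function(dataset, path) {
  v <- dataset$variants
  calls <- dataset$calls
  depth <- dataset$depth
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=chipqc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(depth)) {
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
    },
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      if (nrow(calls) > 0) c("FORMAT", dataset$samples$sample_id)
    ), collapse = "\t")
  ), con)
  if (nrow(v) == 0 || nrow(calls) == 0) {
    if (nrow(v) > 0 && nrow(calls) == 0) {
      body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".",
        sep = "\t"
      )
      writeLines(body, con)
    }
    return(invisible(path))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[calls + 1L], nrow = nrow(calls))
  gt_str[is.na(calls)] <- "./."
  fmt <- "GT"
  if (!is.null(depth)) {
    dstr <- ifelse(is.na(depth), ".", as.character(depth))
    gt_str <- matrix(paste(gt_str, dstr, sep = ":"), nrow = nrow(calls))
    fmt <- "GT:DP"
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(
      v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", ".", ".",
      fmt, gt_str[, j]
    ), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# -- PLINK text --------------------------------------------------------------

plink_paths <- function(path) {
  base <- sub("\\.(ped|map)$", "", path)
  list(ped = paste0(base, ".ped"), map = paste0(base, ".map"))
}

read_plink_calls <- function(path) {
  p <- plink_paths(path)
  if (!file.exists(p$ped) || !file.exists(p$map)) {
    abort(paste0("need both ", p$ped, " and ", p$map))
  }
  map <- utils::read.table(p$map, stringsAsFactors = FALSE)
  if (!ncol(map) %in% c(4L, 6L)) {
    abort("malformed .map: expected 4 or 6 whitespace-separated columns.")
  }
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(p$ped, stringsAsFactors = FALSE,
    colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    abort(paste0(
      "malformed .ped: ", ncol(ped), " columns for ", n_snp,
      " mapped SNPs (expected ", 6 + 2 * n_snp, ")."
    ))
  }
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  if (ncol(map) == 6L) {
    names(map)[5:6] <- c("alt", "ref")
  } else {
    # infer polarity: alt = minor allele (ties / monomorphic: alphabetical)
    infer <- function(j) {
      al <- c(a1[, j], a2[, j])
      al <- al[al != "0"]
      u <- sort(unique(al))
      if (length(u) == 0) return(c("N", "A"))
      if (length(u) == 1) return(c(u, setdiff(c("A", "C"), u)[1]))
      cnt <- table(factor(al, levels = u))
      ord <- order(cnt, u) # minor first; alphabetical on ties
      c(u[ord[1]], u[ord[2]])
    }
    pol <- vapply(seq_len(n_snp), infer, character(2))
    map$alt <- pol[1, ]
    map$ref <- pol[2, ]
  }
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snp)
  for (j in seq_len(n_snp)) {
    g1 <- a1[, j]
    g2 <- a2[, j]
    ok <- g1 != "0" & g2 != "0"
    calls[ok, j] <- (g1[ok] == map$alt[j]) + (g2[ok] == map$alt[j])
  }
  ds <- genotype_dataset(
    calls = calls,
    variants = tibble(
      id = as.character(map$id), chrom = as.character(map$chrom),
      pos = as.integer(map$pos), ref = map$ref, alt = map$alt
    ),
    samples = tibble(
      sample_id = ped[, 2],
      population = ifelse(ped[, 1] == ped[, 2], NA_character_, ped[, 1])
    )
  )
  list(dataset = ds, depth = NULL)
}

write_plink_calls <- function(dataset, path) {
  p <- plink_paths(path)
  v <- dataset$variants
  calls <- dataset$calls
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$alt, v$ref),
    p$map, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n_snp <- nrow(v)
  geno <- matrix("0\t0", nrow = nrow(calls), ncol = n_snp)
  for (j in seq_len(n_snp)) {
    gg <- c(
      paste(v$ref[j], v$ref[j], sep = "\t"),
      paste(v$ref[j], v$alt[j], sep = "\t"),
      paste(v$alt[j], v$alt[j], sep = "\t")
    )[calls[, j] + 1L]
    gg[is.na(gg)] <- "0\t0"
    geno[, j] <- gg
  }
  fid <- dataset$samples$population
  fid[is.na(fid)] <- dataset$samples$sample_id[is.na(fid)]
  lines <- paste(fid, dataset$samples$sample_id, 0, 0, 0, -9,
    if (n_snp > 0) apply(geno, 1, paste, collapse = "\t") else "",
    sep = "\t"
  )
  lines <- sub("\t$", "", lines)
  writeLines(lines, p$ped)
  invisible(path)
}

# -- wide TSV ----------------------------------------------------------------

read_tsv_calls <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "category")
  miss <- setdiff(c("id", "chrom", "pos", "ref", "alt"), names(tb))
  if (length(miss)) {
    abort(paste0("TSV lacks column(s): ", paste(miss, collapse = ", ")))
  }
  samp <- setdiff(names(tb), meta_cols)
  calls <- t(as.matrix(tb[, samp, drop = FALSE]))
  storage.mode(calls) <- "integer"
  ds <- genotype_dataset(
    calls = calls,
    variants = tb[, intersect(meta_cols, names(tb))],
    samples = tibble(sample_id = samp)
  )
  list(dataset = ds, depth = NULL)
}

write_tsv_calls <- function(dataset, path) {
  v <- select(dataset$variants, "id", "chrom", "pos", "ref", "alt",
    "category")
  wide <- as_tibble(t(dataset$calls))
  names(wide) <- dataset$samples$sample_id
  readr::write_tsv(dplyr::bind_cols(v, wide), path)
  invisible(path)
}

# -- auxiliary tables --------------------------------------------------------

#' Read a scaffold-order table
#'
#' Tab-separated, columns `scaffold`, `length`, `chrom`, listed in assembly
#' order; used by [chromosome_scale()] to build chromosome-scale
#' coordinates.
#'
#' @param path TSV path.
#' @return Tibble with the three columns, in file order.
#' @export
read_scaffold_order <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("scaffold", "length", "chrom"), names(tb))
  if (length(miss)) {
    abort(paste0("scaffold table lacks: ", paste(miss, collapse = ", ")))
  }
  if (any(tb$length <= 0)) abort("scaffold lengths must be positive.")
  if (anyDuplicated(tb$scaffold)) abort("duplicate scaffold id.")
  tb
}

#' Read a pedigree table
#'
#' Long tab-separated format: columns `family_id`, `sample_id`, `role`
#' (`parent1`, `parent2` or `offspring`), one row per individual.
#'
#' @param path TSV path.
#' @return Tibble of the pedigree.
#' @export
read_pedigree <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("family_id", "sample_id", "role"), names(tb))
  if (length(miss)) {
    abort(paste0("pedigree lacks: ", paste(miss, collapse = ", ")))
  }
  if (!all(tb$role %in% c("parent1", "parent2", "offspring"))) {
    abort("pedigree roles must be parent1/parent2/offspring.")
  }
  tb
}
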