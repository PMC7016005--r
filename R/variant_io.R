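# Readers/writers for variant tables, genotype panels and peptide FASTA,
# plus accessors for the fixtures bundled with the package.

#' Construct and validate a variant table
#'
#' A variant table is a plain data.frame with one row per called variant and
#' the columns \code{chrom}, \code{start}, \code{end}, \code{ref}, \code{alt},
#' \code{alt_reads}, \code{depth}, \code{fraction}, \code{location_class},
#' \code{effect_class}, \code{gene}, plus the two carried-through booleans
#' \code{validated_by_sanger} and \code{present_in_backcross_affected}.
#' Coordinates are 1-based inclusive; \code{fraction} is
#' \code{alt_reads/depth}, the alternate-allele fraction.
#'
#' @param df data.frame holding at least \code{chrom}, \code{start},
#'   \code{end}, \code{ref}, \code{alt} and one of \code{fraction} or
#'   \code{alt_reads} together with \code{depth}.
#' @return the validated data.frame with all canonical columns, class
#'   \code{variant_table}.
#' @export
as_variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (is.null(df$depth)) df$depth <- NA_integer_
  df$depth <- as.integer(df$depth)
  if (is.null(df$alt_reads)) {
    # tsv_table2 prints only fraction and depth; keep the printed fraction
    df$alt_reads <- as.integer(round(df$fraction * df$depth))
  }
  df$alt_reads <- as.integer(df$alt_reads)
  have_both <- !is.na(df$alt_reads) & !is.na(df$depth)
  if (is.null(df$fraction)) df$fraction <- rep(NA_real_, nrow(df))
  fill <- is.na(df$fraction) & have_both
  df$fraction[fill] <- df$alt_reads[fill] / df$depth[fill]
  off <- have_both & !is.na(df$fraction) &
    abs(df$fraction - df$alt_reads / df$depth) > 0.5 / df$depth
  if (any(off)) stop("fraction inconsistent with alt_reads/depth at row ",
                     which(off)[1], call. = FALSE)
  if (is.null(df$location_class)) df$location_class <- "exonic"
  if (is.null(df$effect_class)) df$effect_class <- "unknown"
  if (is.null(df$gene)) df$gene <- ""
  df$gene <- ifelse(is.na(df$gene), "", as.character(df$gene))
  if (is.null(df$validated_by_sanger)) {
    df$validated_by_sanger <- rep(NA, nrow(df))
  }
  if (is.null(df$present_in_backcross_affected)) {
    df$present_in_backcross_affected <- rep(NA, nrow(df))
  }
  bad_loc <- !(df$location_class %in% .location_classes)
  if (any(bad_loc)) stop("unknown location_class: ",
                         paste(unique(df$location_class[bad_loc]),
                               collapse = ", "), call. = FALSE)
  bad_eff <- !(df$effect_class %in% .effect_classes)
  if (any(bad_eff)) stop("unknown effect_class: ",
                         paste(unique(df$effect_class[bad_eff]),
                               collapse = ", "), call. = FALSE)
  if (any(df$start > df$end)) stop("start > end", call. = FALSE)
  frac_bad <- !is.na(df$fraction) & (df$fraction < 0 | df$fraction > 1)
  if (any(frac_bad)) stop("fraction outside [0, 1]", call. = FALSE)
  cols <- c("chrom", "start", "end", "ref", "alt", "alt_reads", "depth",
            "fraction", "location_class", "effect_class", "gene",
            "validated_by_sanger", "present_in_backcross_affected")
  df <- df[, cols]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a variant call table
#'
#' Two dialects are supported: \code{"tsv_table2"}, a tab-separated table
#' with header \code{chr start end ref alt location gene fraction depth
#' validated appearance} (alternate-read counts are recovered as
#' \code{round(fraction * depth)}), and \code{"vcf_min"}, a minimal VCF v4.x
#' with INFO keys \code{DP} (depth), \code{AO} or \code{AD} (alt reads),
#' \code{LOC} (location class), \code{EFF} (effect class) and \code{GENE}.
#'
#' In the tsv_table2 dialect exonic rows are assigned effect class
#' \code{nonsynonymous} unless an optional \code{effect} column is present:
#' every exonic candidate this table format mirrors was a Sanger-validated
#' nonsynonymous change.
#'
#' @param path file path.
#' @param dialect one of \code{"tsv_table2"}, \code{"vcf_min"}.
#' @return a \code{variant_table} (see [as_variant_table()]).
#' @export
read_variant_table <- function(path, dialect = c("tsv_table2", "vcf_min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv_table2") .read_tsv_table2(path) else .read_vcf_min(path)
}

.read_tsv_table2 <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("chr", "start", "end", "ref", "alt", "location", "gene",
            "fraction", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parse error in ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    return(as_variant_table(data.frame(
      chrom = character(), start = integer(), end = integer(),
      ref = character(), alt = character(), fraction = numeric(),
      depth = integer(), location_class = character(),
      effect_class = character(), gene = character())))
  }
  bad <- which(!(df$location %in% .location_classes))
  if (length(bad)) stop("parse error in ", path, " line ", bad[1] + 1,
                        ": unknown location_class '", df$location[bad[1]],
                        "'", call. = FALSE)
  eff <- if ("effect" %in% names(df)) df$effect else
    ifelse(df$location == "exonic", "nonsynonymous", "unknown")
  yn <- function(x) if (is.null(x)) NA else toupper(as.character(x)) %in%
    c("YES", "TRUE", "1")
  as_variant_table(data.frame(
    chrom = as.character(df$chr), start = df$start, end = df$end,
    ref = df$ref, alt = df$alt, fraction = df$fraction, depth = df$depth,
    location_class = df$location, effect_class = eff, gene = df$gene,
    validated_by_sanger = yn(df$validated),
    present_in_backcross_affected = yn(df$appearance),
    stringsAsFactors = FALSE))
}

.info_get <- function(vcf, key) {
  suppressWarnings(vcfR::extract.info(vcf, element = key))
}

.read_vcf_min <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  fx <- vcf@fix
  if (is.null(fx) || nrow(fx) == 0) {
    return(as_variant_table(data.frame(
      chrom = character(), start = integer(), end = integer(),
      ref = character(), alt = character(), alt_reads = integer(),
      depth = integer(), location_class = character(),
      effect_class = character(), gene = character())))
  }
  dp <- as.integer(.info_get(vcf, "DP"))
  ao <- .info_get(vcf, "AO")
  if (all(is.na(ao))) ao <- .info_get(vcf, "AD")
  ao <- as.integer(ao)
  loc <- .info_get(vcf, "LOC")
  eff <- .info_get(vcf, "EFF")
  gene <- .info_get(vcf, "GENE")
  val <- .info_get(vcf, "VAL")
  app <- .info_get(vcf, "APP")
  yn <- function(x) ifelse(is.na(x), NA, x %in% c("1", "Yes", "TRUE"))
  start <- as.integer(fx[, "POS"])
  as_variant_table(data.frame(
    chrom = fx[, "CHROM"], start = start,
    end = start + nchar(fx[, "REF"]) - 1L,
    ref = fx[, "REF"], alt = fx[, "ALT"], alt_reads = ao, depth = dp,
    location_class = ifelse(is.na(loc), "exonic", loc),
    effect_class = ifelse(is.na(eff), "unknown", eff),
    gene = ifelse(is.na(gene), "", gene),
    validated_by_sanger = yn(val), present_in_backcross_affected = yn(app),
    stringsAsFactors = FALSE))
}

#' Write a variant call table
#'
#' Inverse of [read_variant_table()] for both dialects; a write-then-read
#' round trip reproduces every field.
#'
#' @param x a \code{variant_table}.
#' @param path output file path.
#' @param dialect one of \code{"tsv_table2"}, \code{"vcf_min"}.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(x, path,
                                dialect = c("tsv_table2", "vcf_min")) {
  dialect <- match.arg(dialect)
  x <- as_variant_table(x)
  if (dialect == "tsv_table2") {
    yn <- function(v) ifelse(is.na(v), "NA", ifelse(v, "Yes", "No"))
    out <- data.frame(
      chr = x$chrom, start = x$start, end = x$end, ref = x$ref, alt = x$alt,
      location = x$location_class, gene = x$gene,
      fraction = x$fraction, depth = x$depth, validated = yn(x$validated_by_sanger),
      appearance = yn(x$present_in_backcross_affected),
      effect = x$effect_class, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    info <- paste0(
      "DP=", x$depth, ";AO=", x$alt_reads, ";LOC=", x$location_class,
      ";EFF=", x$effect_class,
      ifelse(nzchar(x$gene), paste0(";GENE=", x$gene), ""),
      ifelse(is.na(x$validated_by_sanger), "",
             paste0(";VAL=", as.integer(x$validated_by_sanger))),
      ifelse(is.na(x$present_in_backcross_affected), "",
             paste0(";APP=", as.integer(x$present_in_backcross_affected))))
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
      "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
      "##INFO=<ID=LOC,Number=1,Type=String,Description=\"Location class\">",
      "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=VAL,Number=1,Type=Integer,Description=\"Sanger validated\">",
      "##INFO=<ID=APP,Number=1,Type=Integer,Description=\"Present in backcross affected\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      if (nrow(x)) paste(x$chrom, x$start, ".", x$ref, x$alt, ".", "PASS",
                         info, sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Construct a segregation panel
#'
#' @param mice data.frame with columns \code{mouse_id}, \code{phenotype}
#'   (\code{"affected"}/\code{"unaffected"}) and optionally
#'   \code{generation} and \code{laterality} (\code{"bilateral"},
#'   \code{"unilateral"}, \code{"none"}, \code{"unknown"}).
#' @param variants character vector of variant identifiers.
#' @param calls character matrix over \code{c("+", "-", "?")}, rows =
#'   variants, columns = mice.
#' @return object of class \code{segregation_panel}.
#' @export
segregation_panel <- function(mice, variants, calls) {
  stopifnot(is.data.frame(mice), all(c("mouse_id", "phenotype") %in%
                                       names(mice)))
  mice$phenotype <- tolower(mice$phenotype)
  stopifnot(all(mice$phenotype %in% c("affected", "unaffected")))
  if (is.null(mice$generation)) mice$generation <- NA_character_
  if (is.null(mice$laterality)) mice$laterality <- "unknown"
  if (length(calls) != length(variants) * nrow(mice)) {
    stop("calls/mice dimension mismatch", call. = FALSE)
  }
  calls <- matrix(normalize_genotype(as.character(calls)),
                  nrow = length(variants), ncol = nrow(mice),
                  dimnames = list(variants, mice$mouse_id))
  structure(list(mice = mice, variants = variants, calls = calls),
            class = "segregation_panel")
}

#' @export
print.segregation_panel <- function(x, ...) {
  cat("segregation_panel:", length(x$variants), "variants x",
      nrow(x$mice), "mice (",
      sum(x$mice$phenotype == "affected"), "affected /",
      sum(x$mice$phenotype == "unaffected"), "unaffected );",
      sum(x$calls == "?"), "missing calls\n")
  invisible(x)
}

#' Read a genotype/phenotype panel
#'
#' Expects a tab-separated file whose first header row carries mouse ids,
#' second header row the phenotypes (\code{Aff}/\code{Unaff}), followed by
#' one row per variant of genotype symbols \code{+}, \code{-}/\code{−}
#' (Unicode minus accepted) and \code{?}.
#'
#' @param path TSV file path.
#' @return a \code{segregation_panel}.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("parse error in ", path,
                              ": need 2 header rows and >=1 variant row",
                              call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    stop("parse error in ", path, " line ",
         which(widths != widths[1])[1], ": inconsistent row width",
         call. = FALSE)
  }
  ids <- cells[[1]][-1]
  phen <- tolower(cells[[2]][-1])
  phen <- ifelse(phen %in% c("aff", "affected"), "affected",
                 ifelse(phen %in% c("unaff", "unaffected"), "unaffected",
                        phen))
  if (!all(phen %in% c("affected", "unaffected"))) {
    stop("parse error in ", path, ": bad phenotype header", call. = FALSE)
  }
  body <- cells[-(1:2)]
  variants <- vapply(body, `[`, "", 1)
  calls <- do.call(rbind, lapply(seq_along(body), function(i) {
    row <- body[[i]][-1]
    tryCatch(normalize_genotype(row), error = function(e)
      stop("parse error in ", path, " line ", i + 2, ": ",
           conditionMessage(e), call. = FALSE))
  }))
  segregation_panel(
    data.frame(mouse_id = ids, phenotype = phen, stringsAsFactors = FALSE),
    variants, calls)
}

#' Write a genotype/phenotype panel
#'
#' @param panel a \code{segregation_panel}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  lines <- c(
    paste(c("variant", panel$mice$mouse_id), collapse = "\t"),
    paste(c("phenotype",
            ifelse(panel$mice$phenotype == "affected", "Aff", "Unaff")),
          collapse = "\t"),
    vapply(seq_along(panel$variants), function(i)
      paste(c(panel$variants[i], panel$calls[i, ]), collapse = "\t"), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file; sequences must use the uppercase 20-letter
#'   amino-acid alphabet.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e),
                                          call. = FALSE))
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) stop("parse error in ", path,
                               ": empty sequence record", call. = FALSE)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (!all(ok)) stop("parse error in ", path,
                     ": non-amino-acid character in record ",
                     names(aa)[!ok][1], call. = FALSE)
  data.frame(id = names(aa), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write peptide sequences to FASTA
#'
#' @param peptides data.frame with columns \code{id}, \code{sequence}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  aa <- Biostrings::AAStringSet(peptides$sequence)
  names(aa) <- peptides$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Path to a bundled fixture
#'
#' Bundled fixtures: \code{"table1_panel.tsv"} (the 16-candidate genotype
#' panel over 7 affected and 5 unaffected mice), \code{"table2_variants.tsv"}
#' (the four chromosome-12 variants with allelic fractions, depths and
#' backcross appearance), \code{"ta_domain.fa"} (the 13-residue Twist1
#' transactivation-domain peptide, protein positions 185-197) and
#' \code{"chou_fasman_helix.tsv"} (the Chou-Fasman alpha-helix propensity
#' scale).
#'
#' @param name fixture file name.
#' @return absolute file path.
#' @export
enu_fixture <- function(name) {
  p <- system.file("extdata", name, package = "enuscan")
  if (!nzchar(p)) stop("no bundled fixture named ", name, call. = FALSE)
  p
}

#' The bundled candidate genotype panel
#' @return a \code{segregation_panel} with 16 variants and 12 mice.
#' @export
table1_panel <- function() read_panel(enu_fixture("table1_panel.tsv"))

#' The bundled chromosome-12 variant table
#' @return a \code{variant_table} with 4 rows.
#' @export
table2_variants <- function()
  read_variant_table(enu_fixture("table2_variants.tsv"), "tsv_table2")

#' The bundled transactivation-domain peptide
#' @return list with \code{id}, \code{sequence} and \code{offset} (185).
#' @export
ta_domain_peptide <- function() {
  p <- read_peptides(enu_fixture("ta_domain.fa"))
  list(id = p$id[1], sequence = p$sequence[1], offset = 185L)
}
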