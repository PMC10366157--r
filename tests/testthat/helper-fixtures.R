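# small pedigrees built in code, shared across test files

trioDf <- function() {
  data.frame(fid = "F1", iid = c("dad", "mum", "kid"),
             pat = c(NA, NA, "dad"), mat = c(NA, NA, "mum"),
             sex = c("male", "female", "female"),
             stringsAsFactors = FALSE)
}

# founder couple + 2 girls + 1 boy
nuclearDf <- function() {
  data.frame(fid = "N1",
             iid = c("pa", "ma", "g1", "g2", "b1"),
             pat = c(NA, NA, "pa", "pa", "pa"),
             mat = c(NA, NA, "ma", "ma", "ma"),
             sex = c("male", "female", "female", "female", "male"),
             stringsAsFactors = FALSE)
}

# three generations incl. avuncular, grandparent, cousins, half-sibs
extendedDf <- function() {
  data.frame(fid = "E1",
    iid = c("gpa", "gma", "f1", "f2", "aunt", "w1", "w2", "c1", "c2",
            "other", "h1"),
    pat = c(NA, NA, "gpa", "gpa", "gpa", NA, NA, "f1", "f2", NA, "f1"),
    mat = c(NA, NA, "gma", "gma", "gma", NA, NA, "w1", "w2", NA, "other"),
    sex = c("male", "female", "male", "male", "female", "female", "female",
            "male", "female", "female", "male"),
    stringsAsFactors = FALSE)
}

writePedFile <- function(df, sep = " ", header = FALSE) {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  out <- data.frame(df$fid, df$iid,
                    ifelse(is.na(df$pat), "0", df$pat),
                    ifelse(is.na(df$mat), "0", df$mat),
                    ifelse(df$sex == "male", 1L,
                           ifelse(df$sex == "female", 2L, 0L)))
  if (header) names(out) <- c("FID", "IID", "PAT", "MAT", "SEX")
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = header)
  path
}

# phenotype table in prepared state directly from given values
preparedTable <- function(ids, values, fid = NULL) {
  d <- data.frame(individual_id = ids, age = 40, sex = "female",
                  energy = 2000, trait = values,
                  stringsAsFactors = FALSE)
  if (!is.null(fid)) d$fid <- fid
  pt <- phenotypeTable(d, traits = "trait")
  methods::initialize(pt, state = "prepared")
}

# pair table rows for a single class
pairTable <- function(id_a, id_b, cls, fid = seq_along(id_a)) {
  data.frame(fid = as.character(fid), id_a = id_a, id_b = id_b,
             pair_class = cls, degree = "first", stringsAsFactors = FALSE)
}
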