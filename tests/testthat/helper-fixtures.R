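# Fixtures built in code: a tiny hand-written bundle exercising the parsing
# and dedup contracts, plus shared study configuration.

tiny_tables <- function() {
  demo <- data.frame(
    primaryid = c(5550001, 5550002, 5560001, 5570001, 5580001),
    caseid = c(555, 555, 556, 557, 558),
    event_dt = c("20180324", "20180324", "2018", "20190501", ""),
    fda_dt = c("20180401", "20180405", "20180601", "20190520", "20200101"),
    age = c("62", "63", "744", "45", ""),
    age_cod = c("YR", "YR", "MON", "YR", "YR"),
    sex = c("F", "F", "M", "F", ""),
    wt = c("", "", "212", "80", ""),
    wt_cod = c("", "", "LBS", "KG", ""),
    reporter_country = c("US", "US", "GB", "US", "US"),
    occp_cod = c("MD", "MD", "CN", "CN", ""),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c(5550001, 5550002, 5560001, 5560001, 5570001, 5580001),
    caseid = c(555, 555, 556, 556, 557, 558),
    drug_seq = c("1", "1", "1", "2", "1", "1"),
    role_cod = c("PS", "PS", "PS", "C", "C", "PS"),
    drugname = c("OZEMPIC", "ozempic ", "SEMAGLUTIDE", "METFORMIN", "ASPIRIN",
                 "IBUPROFEN"),
    prod_ai = c("SEMAGLUTIDE", "SEMAGLUTIDE", "SEMAGLUTIDE", "METFORMIN",
                "SEMAGLUTIDE", "IBUPROFEN"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c(5550001, 5550002, 5550002, 5560001, 5570001, 5580001),
    caseid = c(555, 555, 555, 556, 557, 558),
    pt = c("Nausea", "Nausea", "Vomiting", "Pancreatitis", "Nausea",
           "Headache"),
    stringsAsFactors = FALSE)
  outc <- data.frame(
    primaryid = c(5560001, 5560001, 5580001),
    caseid = c(556, 556, 558),
    outc_cod = c("HO", "OT", "DE"),
    stringsAsFactors = FALSE)
  ther <- data.frame(
    primaryid = c(5550002, 5560001, 5580001),
    caseid = c(555, 556, 558),
    dsg_drug_seq = c("1", "1", "1"),
    start_dt = c("20180301", "201803", "20191201"),
    stringsAsFactors = FALSE)
  indi <- data.frame(
    primaryid = 5550002, caseid = 555, indi_drug_seq = "1",
    indi_pt = "Type 2 diabetes mellitus", stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
       indi = indi)
}

tiny_bundle <- function(deleted = numeric(0)) {
  as_faers_bundle(tiny_tables(), deleted_caseids = deleted)
}

sema_config <- function(...) {
  study_config("SEMAGLUTIDE", c("OZEMPIC", "RYBELSUS", "WEGOVY"), ...)
}

gi_map <- function() {
  read_pt_soc_map(system.file("extdata", "gi_pt_soc_map.csv",
                              package = "faersignal"))
}

gi_features <- function() {
  utils::read.csv(system.file("extdata", "semaglutide_gi_signal_features.csv",
                              package = "faersignal"),
                  stringsAsFactors = FALSE)
}

gi_severity <- function() {
  utils::read.csv(system.file("extdata", "semaglutide_gi_severity_counts.csv",
                              package = "faersignal"),
                  stringsAsFactors = FALSE)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration (oracle)
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
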