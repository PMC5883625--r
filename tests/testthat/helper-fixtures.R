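# Shared fixtures, built once per test run.

reduced_model_fixture <- build_reduced_model()

# Linear chain glc_e -> A -> B -> out, uptake-limited. The uptake exchange
# is named EX_glc so the route-scan machinery can treat it as the carbon
# source; all species are C1 so every internal reaction is balanced.
chain_model <- function(uptake = 10, mid_upper = 1000) {
  c1 <- c(C = 1, H = 2, O = 1)
  metabolic_model(
    list(metabolite("glc_e", compartment = "extracellular", formula = c1),
         metabolite("A", formula = c1),
         metabolite("B", formula = c1),
         metabolite("P_e", compartment = "extracellular", formula = c1)),
    list(reaction("EX_glc", c(glc_e = -1), lower_bound = -uptake,
                  upper_bound = 0, kind = "exchange"),
         reaction("T_in", c(glc_e = -1, A = 1)),
         reaction("MID", c(A = -1, B = 1), upper_bound = mid_upper),
         reaction("T_out", c(B = -1, P_e = 1)),
         reaction("EX_P", c(P_e = -1), kind = "exchange")),
    objective_id = "EX_P")
}

# small intensity table with explicit values for hand-checked statistics
toy_table <- function(values, groups, standards = character()) {
  n <- ncol(values)
  design <- data.frame(
    sample_id = colnames(values),
    carbon_source = sub("_.*", "", groups),
    timepoint_h = as.numeric(sub(".*_", "", groups)),
    replicate = stats::ave(seq_len(n), groups, FUN = seq_along))
  intensity_table(values, design, internal_standard_ids = standards)
}
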