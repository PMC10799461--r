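# shared fixtures, all built in code

# constant-mortality life table (same q at every age, both sexes)
flat_life_table <- function(q = 0.001, min_age = 50, max_age = 110) {
  ages <- seq(min_age, max_age - 1)
  life_table(data.frame(
    age = rep(c(ages, max_age), 2),
    sex = rep(c("female", "male"), each = length(ages) + 1),
    q_annual = rep(c(rep(q, length(ages)), 1), 2)),
    max_age = max_age)
}

# immortal table: background mortality zero everywhere below the terminal age
zero_life_table <- function(min_age = 50, max_age = 110) {
  flat_life_table(q = 0, min_age = min_age, max_age = max_age)
}

# fracture model with every probability zero (SMRs irrelevant)
zero_fracture_model <- function() {
  z <- matrix(0, 4, 2, dimnames = list(c("S", "D", "I_mid", "I_high"),
                                       c("treated", "discontinued")))
  fracture_model(p_vf = z, p_nvf = z,
                 smr_vf = c(female = 1, male = 1),
                 smr_nvf = c(female = 1, male = 1))
}

# strategy with no transitions at all (stay in S forever)
inert_strategy <- function(drug = NA_character_) {
  strategy_spec("inert", treatment_duration_cycles = "lifetime",
                tp_S_to_I = 0, tp_D_to_I = 0,
                on_treatment_drug = drug)
}

# flat productivity profile for hand-computable losses
flat_profile <- function(income = 30e6, employment = 0.5,
                         retirement_age = 65, min_age = 20) {
  ages <- seq(min_age, retirement_age)
  inc <- rep(income, length(ages))
  emp <- rep(employment, length(ages))
  names(inc) <- names(emp) <- ages
  productivity_profile(inc, emp, retirement_age = retirement_age)
}
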