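# Macro-economic inputs for the 2015 South African analysis.
# gdp_per_capita is left null here: the default accessor derives it from the
# bundled burden table (total economic value / total DALY loss), the single
# rate consistent with that table's cells.
gdp_per_capita: null
gdp_total: 4.013e+12          # nominal GDP, ZAR
median_monthly_earnings_base: 3120   # median monthly earnings, 2014 ZAR
earnings_target_year: 3262    # the same earnings expressed in 2015 ZAR
labour_force: 21084500        # average labour-force size, 2015
exchange_rate: 12.8           # ZAR per USD, 2015 (report column only)
homicide_reference_year: 2009
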