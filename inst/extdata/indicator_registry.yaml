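# Default climate-and-health indicator registry for a rural district.
# Hazard membership follows the indicator-to-hazard superscript convention
# (heat / drought / flood); direction says which side of a reference is
# worse. Standard values are policy inputs and are intentionally unset.
indicators:
  - id: heat_waves
    name: Exposure to heat waves
    category: environmental_exposure
    hazards: [heat]
    direction: higher_is_worse
  - id: heavy_precip
    name: Exposure to heavy precipitation events
    category: environmental_exposure
    hazards: [flood]
    direction: higher_is_worse
  - id: drought_exposure
    name: Exposure to drought (weeks at D2 or worse)
    category: environmental_exposure
    hazards: [drought]
    direction: higher_is_worse
  - id: air_pollution_pm25
    name: Exposure to air pollution (annual mean PM2.5, ug/m3)
    category: environmental_exposure
    hazards: [drought]
    direction: higher_is_worse
    standard:
      source: US EPA 2012 annual fine-particulate standard
  - id: heat_morbidity_mortality
    name: Heat-related morbidity and mortality during extreme heat events
    category: health_outcome
    hazards: [heat]
    direction: higher_is_worse
  - id: flood_mortality
    name: Unintentional flooding-related mortality
    category: health_outcome
    hazards: [flood]
    direction: higher_is_worse
  - id: flood_morbidity
    name: Unintentional flooding-related morbidity
    category: health_outcome
    hazards: [flood]
    direction: higher_is_worse
  - id: children
    name: Children (share of population)
    category: population_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
  - id: elderly
    name: Elderly, aged 65+ (share of population)
    category: population_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
  - id: poverty
    name: Population living in poverty
    category: population_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
  - id: non_hispanic_black
    name: Non-Hispanic Black population
    category: population_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
  - id: outdoor_workers
    name: Outdoor workers
    category: population_vulnerability
    hazards: [heat]
    direction: higher_is_worse
  - id: limited_english
    name: Limited English proficiency
    category: population_vulnerability
    hazards: [flood]
    direction: higher_is_worse
  - id: ambulatory_difficulty
    name: Ambulatory difficulty
    category: population_vulnerability
    hazards: [flood]
    direction: higher_is_worse
  - id: homeless
    name: Homeless population
    category: population_vulnerability
    hazards: [heat]
    direction: higher_is_worse
  - id: long_term_care
    name: Long-term care facility residents
    category: population_vulnerability
    hazards: [flood]
    direction: higher_is_worse
  - id: clrd
    name: Chronic lower respiratory disease
    category: population_vulnerability
    hazards: [drought]
    direction: higher_is_worse
  - id: diabetes
    name: Diabetes prevalence
    category: population_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
  - id: heart_disease
    name: Heart disease mortality
    category: population_vulnerability
    hazards: [heat]
    direction: higher_is_worse
    standard:
      source: Healthy People 2020 Goal HDS-2
  - id: cerebrovascular_disease
    name: Cerebrovascular disease deaths
    category: population_vulnerability
    hazards: [heat]
    direction: higher_is_worse
    standard:
      source: Healthy People 2020 Goal HDS-3
  - id: mental_health
    name: Mental health service need
    category: population_vulnerability
    hazards: [drought, flood]
    direction: higher_is_worse
  - id: obesity
    name: Obesity prevalence
    category: population_vulnerability
    hazards: [heat]
    direction: higher_is_worse
    standard:
      source: Healthy People 2020 Goal NWS-9
  - id: asthma
    name: Asthma hospitalizations
    category: population_vulnerability
    hazards: [heat, drought]
    direction: higher_is_worse
    standard:
      source: Healthy People 2020 Goal RD-2.2
  - id: floodplain
    name: Population in the FEMA 100-year floodplain (%)
    category: environmental_vulnerability
    hazards: [flood]
    direction: higher_is_worse
  - id: ac_access
    name: Air conditioning access
    category: environmental_vulnerability
    hazards: [heat]
    direction: lower_is_worse
  - id: co_poisoning
    name: Carbon monoxide poisoning
    category: environmental_vulnerability
    hazards: [heat, flood]
    direction: higher_is_worse
  - id: stressed_housing
    name: Stressed housing
    category: environmental_vulnerability
    hazards: [heat, drought, flood]
    direction: higher_is_worse
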