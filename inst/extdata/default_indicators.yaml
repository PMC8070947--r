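# Default 23-indicator E-S-A configuration for high-intensity-development
# islands (expert-survey weights; element sums reflect two-decimal rounding
# and are renormalized at aggregation time). Standards marked NA (stepwise
# area classes, environmental-quality grades) must be set per study area.
indicators:
  - {id: C1,  element: B1, name: Impact of typical natural disasters,       polarity: negative, weight: 0.34, spatial_mode: uniform}
  - {id: C2,  element: B1, name: Island area change rate,                   polarity: negative, weight: 0.24, spatial_mode: uniform}
  - {id: C3,  element: B1, name: Change rate of island shoreline,           polarity: negative, weight: 0.23, spatial_mode: uniform}
  - {id: C4,  element: B1, name: Proportion of steep slope area,            polarity: negative, weight: 0.20, spatial_mode: heterogeneous, standard: NA}
  - {id: C5,  element: B2, name: Population density of residents,           polarity: negative, weight: 0.14, spatial_mode: uniform}
  - {id: C6,  element: B2, name: Tourism population pressure,               polarity: negative, weight: 0.15, spatial_mode: uniform}
  - {id: C7,  element: B2, name: Impact of man-made environmental disturbance, polarity: negative, weight: 0.17, spatial_mode: uniform}
  - {id: C8,  element: B2, name: Island land development impact,            polarity: negative, weight: 0.20, spatial_mode: heterogeneous}
  - {id: C9,  element: B2, name: Shoreline development impact,              polarity: negative, weight: 0.18, spatial_mode: heterogeneous}
  - {id: C10, element: B2, name: Impact of surrounding sea area development, polarity: negative, weight: 0.15, spatial_mode: heterogeneous}
  - {id: C11, element: B3, name: Net primary productivity of vegetation,    polarity: negative, weight: 0.56, spatial_mode: heterogeneous}
  - {id: C12, element: B3, name: Primary productivity of surrounding sea,   polarity: negative, weight: 0.44, spatial_mode: heterogeneous}
  - {id: C13, element: B4, name: Groundwater environmental quality,         polarity: negative, weight: 0.25, spatial_mode: heterogeneous, standard: NA}
  - {id: C14, element: B4, name: Soil environmental quality,                polarity: negative, weight: 0.29, spatial_mode: heterogeneous, standard: NA}
  - {id: C15, element: B4, name: Sea water environmental quality,           polarity: negative, weight: 0.28, spatial_mode: heterogeneous, standard: NA}
  - {id: C16, element: B4, name: Marine sediments environmental quality,    polarity: negative, weight: 0.19, spatial_mode: heterogeneous, standard: NA}
  - {id: C17, element: B5, name: Island area,                               polarity: positive, weight: 0.54, spatial_mode: uniform}
  - {id: C18, element: B5, name: Island shape complexity,                   polarity: negative, weight: 0.46, spatial_mode: uniform}
  - {id: C19, element: B6, name: Income level of residents,                 polarity: positive, weight: 0.28, spatial_mode: uniform}
  - {id: C20, element: B6, name: Science and technology support capacity,   polarity: positive, weight: 0.37, spatial_mode: uniform}
  - {id: C21, element: B6, name: Education level of residents,              polarity: positive, weight: 0.35, spatial_mode: uniform}
  - {id: C22, element: B7, name: Treatment capacity of main pollutants,     polarity: positive, weight: 1.00, spatial_mode: uniform, standard: 0.9}
  - {id: C23, element: B8, name: Management effectiveness,                  polarity: positive, weight: 1.00, spatial_mode: uniform}
class_breaks: [0.6, 0.7, 0.9, 1.0]
leveling:
  default: [0.6, 0.7]
  C14: [0.24, 0.25]
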