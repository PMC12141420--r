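# Canonical country name -> additional aliases (the canonical name itself is
# always matched).  Matching is token-boundary anchored and case-insensitive,
# except for aliases listed under `ambiguous`, which are also common English
# words or personal names and are matched only when capitalised in the
# source text.
countries:
  Afghanistan: []
  Albania: []
  Algeria: []
  Angola: []
  Argentina: []
  Armenia: []
  Australia: []
  Austria: []
  Azerbaijan: []
  Bangladesh: []
  Belarus: []
  Belgium: []
  Belize: []
  Benin: []
  Bhutan: []
  Bolivia: []
  Bosnia and Herzegovina: [Bosnia]
  Botswana: []
  Brazil: []
  Bulgaria: []
  Burkina Faso: []
  Burundi: []
  Cambodia: []
  Cameroon: []
  Canada: []
  Chad: []
  Chile: []
  China: [Tibet, Tibetan Plateau]
  Colombia: []
  Costa Rica: []
  Croatia: []
  Cuba: []
  Cyprus: []
  Czech Republic: [Czechia, Czechoslovakia]
  Democratic Republic of the Congo: [DR Congo, Zaire]
  Denmark: []
  Dominican Republic: []
  Ecuador: []
  Egypt: []
  El Salvador: []
  Eritrea: []
  Estonia: []
  Eswatini: [Swaziland]
  Ethiopia: []
  Fiji: []
  Finland: []
  France: []
  Gabon: []
  Gambia: []
  Georgia: []
  Germany: []
  Ghana: []
  Greece: []
  Greenland: []
  Guatemala: []
  Guinea: []
  Guyana: []
  Haiti: []
  Honduras: []
  Hungary: []
  Iceland: []
  India: []
  Indonesia: []
  Iran: [Persia]
  Iraq: []
  Ireland: []
  Israel: []
  Italy: []
  Ivory Coast: [Cote d'Ivoire]
  Jamaica: []
  Japan: []
  Jordan: []
  Kazakhstan: []
  Kenya: []
  Kuwait: []
  Kyrgyzstan: []
  Laos: []
  Latvia: []
  Lebanon: []
  Lesotho: []
  Liberia: []
  Libya: []
  Lithuania: []
  Luxembourg: []
  Madagascar: []
  Malawi: []
  Malaysia: []
  Mali: []
  Malta: []
  Mauritania: []
  Mexico: []
  Moldova: []
  Mongolia: []
  Montenegro: []
  Morocco: []
  Mozambique: []
  Myanmar: [Burma]
  Namibia: []
  Nepal: []
  Netherlands: [Holland]
  New Zealand: []
  Nicaragua: []
  Niger: []
  Nigeria: []
  North Korea: []
  North Macedonia: [Macedonia]
  Norway: []
  Oman: []
  Pakistan: []
  Panama: []
  Papua New Guinea: []
  Paraguay: []
  Peru: []
  Philippines: []
  Poland: []
  Portugal: []
  Qatar: []
  Republic of the Congo: [Congo]
  Romania: []
  Russia: [Russian Federation, Soviet Union, USSR, Siberia]
  Rwanda: []
  Saudi Arabia: []
  Senegal: []
  Serbia: []
  Sierra Leone: []
  Singapore: []
  Slovakia: []
  Slovenia: []
  Somalia: []
  South Africa: []
  South Korea: [Republic of Korea]
  South Sudan: []
  Spain: []
  Sri Lanka: []
  Sudan: []
  Suriname: []
  Sweden: []
  Switzerland: []
  Syria: []
  Taiwan: []
  Tajikistan: []
  Tanzania: []
  Thailand: []
  Togo: []
  Trinidad and Tobago: [Trinidad]
  Tunisia: []
  Turkey: [Turkiye]
  Turkmenistan: []
  Uganda: []
  Ukraine: []
  United Arab Emirates: [UAE]
  United Kingdom: [UK, U.K., Britain, Great Britain, England, Scotland, Wales, Northern Ireland]
  United States: [United States of America, USA, U.S.A., US, U.S., America]
  Uruguay: []
  Uzbekistan: []
  Venezuela: []
  Vietnam: [Viet Nam]
  Yemen: []
  Zambia: []
  Zimbabwe: []
ambiguous: [Georgia, Jordan, Chad, Turkey, US, America, England, Congo]
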