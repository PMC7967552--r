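event_id,date,measure_no,domain,direction,population,specific_group,availability_scope,immediacy,description
LT01,2001-06-01,1,taxation_price,restrictive,general,,none,immediate,Excise tax increase of 6% for ethyl alcohol; change to a taxing format
LT02,2001-11-28,1,availability,liberalizing,general,,outlet_type,immediate,Liberalization of sales and production; sales of alcohol in petrol stations allowed
LT03,2002-06-28,1,availability,liberalizing,general,,production_licensing,immediate,State production monopoly abolished; municipalities allowed to decide on alcohol sales
LT03,2002-06-28,2,marketing_advertising,liberalizing,general,,none,delayed,Liberalization of advertising; fines for violations reduced
LT04,2002-07-01,1,taxation_price,liberalizing,general,,none,immediate,Exemption of excise tax for small breweries
LT05,2003-05-01,1,drink_driving,restrictive,general,,none,immediate,Criminal liability restored in certain cases of harm to individuals or significant property damage
LT06,2003-07-16,1,marketing_advertising,liberalizing,general,,none,delayed,Liberalization of advertising by expanding the range of display places
LT07,2004-01-01,1,taxation_price,liberalizing,general,,none,immediate,Decrease of excise tax for a sub-category of fermented beverages when equalizing with similar categories
LT08,2004-05-01,1,taxation_price,neutral,general,,none,immediate,Four alcohol beverage categories formed; licensing changes on joining the EU
LT09,2008-01-01,1,drink_driving,restrictive,general,,none,immediate,Increased penalties; car confiscation or imprisonment for repeat offenders; lower BAC threshold for novice drivers
LT09,2008-01-01,2,marketing_advertising,restrictive,general,,none,delayed,Advertising banned on TV and radio during daytime
LT09,2008-01-01,3,taxation_price,restrictive,general,,none,immediate,Increase in excise tax by 10-20%
LT10,2009-01-01,1,taxation_price,restrictive,general,,none,immediate,Increase in excise tax by 10-15%; removal of tax exemptions for small beer breweries
LT10,2009-01-01,2,availability,restrictive,general,,specific_days_or_night,immediate,Off-premise sales restricted at night; ban on opened alcohol beverages in cars
LT11,2014-04-01,1,taxation_price,restrictive,general,,none,immediate,Increase in excise tax by 10-47%; 1% for ethyl alcohol
LT12,2015-01-01,1,drink_driving,restrictive,specific,novice and professional drivers,none,immediate,Zero BAC limit for select driver groups
LT13,2015-03-01,1,taxation_price,restrictive,general,,none,immediate,Increase in excise tax of 10-16% for beer wine and intermediate products; 2% for ethyl alcohol
LT14,2016-01-01,1,availability,restrictive,specific,petrol station customers,outlet_type,immediate,Alcohol sales banned at petrol stations
LT15,2016-03-01,1,taxation_price,restrictive,general,,none,immediate,Increase in excise tax by 8% for beer and wine; 2.5% for ethyl alcohol
LT16,2017-01-01,1,drink_driving,restrictive,specific,drivers above 1.5 per-mille BAC,none,immediate,BAC above 1.5 per mille made a criminal offence
LT17,2017-03-01,1,taxation_price,restrictive,general,,none,immediate,Increase in excise tax of 111-112% for wine beer and intermediate products; 23% for ethyl alcohol
LT18,2018-01-01,1,availability,restrictive,general,,daily_hours,immediate,Increase in legal minimum age and enforcement; reduced off-premise sales hours
LT18,2018-01-01,2,marketing_advertising,restrictive,general,,none,delayed,Full ban of TV radio and internet advertisements with few exceptions
LT19,2019-03-01,1,taxation_price,restrictive,general,,none,immediate,10.5% excise increase for ethyl alcohol
LT20,2019-04-01,1,drink_driving,restrictive,specific,drivers refusing police BAC testing,none,immediate,Refusal of BAC testing made a criminal offence (amendment of the 2017 law)
LT21,2019-11-01,1,other,restrictive,general,,none,delayed,Ban on manufacture and sale of child-oriented goods mimicking alcoholic beverages or their packaging
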