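alias	country
China	China
PR China	China
P.R. China	China
People's Republic of China	China
Peoples R China	China
USA	United States
United States	United States
United States of America	United States
U.S.A.	United States
UK	United Kingdom
United Kingdom	United Kingdom
England	United Kingdom
Scotland	United Kingdom
Italy	Italy
Iran	Iran
Islamic Republic of Iran	Iran
Japan	Japan
Germany	Germany
France	France
Australia	Australia
Canada	Canada
South Korea	South Korea
Republic of Korea	South Korea
Korea	South Korea
India	India
Spain	Spain
Netherlands	Netherlands
The Netherlands	Netherlands
Sweden	Sweden
Switzerland	Switzerland
Ireland	Ireland
Czech Republic	Czech Republic
Czechia	Czech Republic
Cyprus	Cyprus
Malaysia	Malaysia
New Zealand	New Zealand
Guatemala	Guatemala
Turkey	Turkey
Brazil	Brazil
Egypt	Egypt
Saudi Arabia	Saudi Arabia
Poland	Poland
Greece	Greece
Austria	Austria
Norway	Norway
Denmark	Denmark
Finland	Finland
Portugal	Portugal
Singapore	Singapore
Taiwan	Taiwan
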